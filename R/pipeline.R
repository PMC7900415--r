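#' Pipeline configuration
#'
#' Collects every tunable knob of the pipeline with its default. All
#' downstream functions take one of these, and runner functions echo the
#' effective configuration next to their outputs so a run is reproducible
#' from its artifacts alone.
#'
#' @param delta semantic contribution factor in (0, 1] (default 0.5).
#' @param gamma_prime_d,gamma_prime_m original interaction-profile kernel
#'   bandwidths (default 1).
#' @param k_neighbors KNN size for fusion; `NULL` means `min(20, n - 1)`.
#' @param t_iter number of fusion diffusion steps (default 20).
#' @param schedule fusion update schedule, `"simultaneous"` or
#'   `"sequential"`.
#' @param symmetrize_each_step stabilize fusion kernels each step.
#' @param rank completion rank; `NULL` means `min(50, nd, nm)`.
#' @param lambda1,lambda2 regularization weights (default 1).
#' @param lambda_mode `"fixed"` uses `lambda1`/`lambda2` as given;
#'   `"scaled"` sets both to `1 / ||A||_F` of the training matrix.
#' @param tol relative-objective convergence threshold (default 1e-6).
#' @param max_iter iteration cap for the solver (default 1000).
#' @param seed master seed for factor initialization and CV partitions.
#' @return an `mda_config` list.
#' @export
mda_config <- function(delta = 0.5, gamma_prime_d = 1, gamma_prime_m = 1,
                       k_neighbors = NULL, t_iter = 20,
                       schedule = c("simultaneous", "sequential"),
                       symmetrize_each_step = TRUE,
                       rank = NULL, lambda1 = 1, lambda2 = 1,
                       lambda_mode = c("fixed", "scaled"),
                       tol = 1e-6, max_iter = 1000, seed = 1) {
  structure(list(delta = delta,
                 gamma_prime_d = gamma_prime_d, gamma_prime_m = gamma_prime_m,
                 k_neighbors = k_neighbors, t_iter = t_iter,
                 schedule = match.arg(schedule),
                 symmetrize_each_step = symmetrize_each_step,
                 rank = rank, lambda1 = lambda1, lambda2 = lambda2,
                 lambda_mode = match.arg(lambda_mode),
                 tol = tol, max_iter = max_iter, seed = seed),
            class = "mda_config")
}

effective_lambdas <- function(A, config) {
  if (config$lambda_mode == "scaled") {
    lam <- 1 / sqrt(sum(as.matrix(A)^2))
    c(lam, lam)
  } else {
    c(config$lambda1, config$lambda2)
  }
}

#' Build the fused disease and miRNA similarity matrices
#'
#' Disease side: semantic similarity from the term DAG fused with the
#' interaction-profile kernel of the association rows. miRNA side: the
#' functional similarity view fused with the interaction-profile kernel of
#' the association columns.
#'
#' @param assoc an `assoc_matrix`.
#' @param mirna_functional miRNA functional `sim_matrix` (ids must match the
#'   association columns).
#' @param dag a `disease_dag` covering the association's diseases; ignored
#'   if `disease_semantic` is given.
#' @param disease_semantic optional precomputed semantic `sim_matrix`.
#' @param config an [mda_config()].
#' @return list with fused `Sd` and `Sm` plus the four input views.
#' @export
build_similarities <- function(assoc, mirna_functional, dag = NULL,
                               disease_semantic = NULL,
                               config = mda_config()) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  DS <- disease_semantic %||%
    semantic_similarity(dag, rownames(assoc), delta = config$delta)
  stopifnot(identical(rownames(DS), rownames(assoc)),
            identical(rownames(mirna_functional), colnames(assoc)))
  GKD <- gip_similarity(assoc, "disease", config$gamma_prime_d)
  GKM <- gip_similarity(assoc, "mirna", config$gamma_prime_m)
  Sd <- snf_fuse(DS, GKD, k = config$k_neighbors, t_iter = config$t_iter,
                 schedule = config$schedule,
                 symmetrize_each_step = config$symmetrize_each_step)
  Sm <- snf_fuse(mirna_functional, GKM, k = config$k_neighbors,
                 t_iter = config$t_iter, schedule = config$schedule,
                 symmetrize_each_step = config$symmetrize_each_step)
  list(Sd = Sd, Sm = Sm, disease_semantic = DS, disease_gip = GKD,
       mirna_functional = mirna_functional, mirna_gip = GKM)
}

#' Run the full prediction pipeline on a dataset
#'
#' Similarity construction, fusion, completion, scoring: the end-to-end
#' composition of the method on one dataset.
#'
#' @param dataset an `mda_dataset`.
#' @param config an [mda_config()].
#' @return an `mda_prediction`: list with `scores` (a `score_matrix`),
#'   `fit` (the `imc_fit`), the fused `Sd`/`Sm`, and the config.
#' @export
mda_predict <- function(dataset, config = mda_config()) {
  stopifnot(inherits(dataset, "mda_dataset"))
  sims <- build_similarities(dataset$assoc, dataset$mirna_functional,
                             dag = dataset$disease_dag, config = config)
  lam <- effective_lambdas(dataset$assoc, config)
  fit <- fit_imc(dataset$assoc, sims$Sd, sims$Sm, rank = config$rank,
                 lambda1 = lam[1L], lambda2 = lam[2L], tol = config$tol,
                 max_iter = config$max_iter, seed = config$seed)
  structure(list(scores = predict(fit, sims$Sd, sims$Sm), fit = fit,
                 Sd = sims$Sd, Sm = sims$Sm, config = config),
            class = "mda_prediction")
}

#' @export
print.mda_prediction <- function(x, ...) {
  cat(sprintf("<mda_prediction> %d x %d scores, solver: %d iterations\n",
              nrow(x$scores), ncol(x$scores), x$fit$n_iterations))
  invisible(x)
}

#' File-driven prediction run
#'
#' Reads the three input artifacts, runs [mda_predict()], and writes the
#' ranked score table, the solver objective trace, and an echo of the
#' effective configuration under `out_dir`.
#'
#' @param assoc_path association edge-list TSV.
#' @param functional_path miRNA functional similarity TSV.
#' @param term_path,edge_path disease term DAG files.
#' @param out_dir output directory.
#' @param config an [mda_config()].
#' @param top_k optional per-disease truncation of the ranking file.
#' @return the `mda_prediction`, invisibly.
#' @export
run_predict <- function(assoc_path, functional_path, term_path, edge_path,
                        out_dir, config = mda_config(), top_k = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  dataset <- stage("read", {
    assoc <- read_associations(assoc_path)
    structure(list(assoc = assoc,
                   mirna_functional = read_similarity(
                     functional_path, expected_ids = colnames(assoc),
                     view = "functional"),
                   disease_dag = read_dag(term_path, edge_path),
                   truth = NULL, seed = config$seed),
              class = "mda_dataset")
  })
  pred <- stage("predict", mda_predict(dataset, config))
  stage("write", {
    write_scores(pred$scores, file.path(out_dir, "scores.tsv"))
    if (!is.null(top_k)) {
      write_scores(pred$scores, file.path(out_dir, "rankings.tsv"),
                   top_k = top_k)
    }
    readr::write_tsv(tidy(pred$fit), file.path(out_dir, "objective_trace.tsv"))
    write_config(config, file.path(out_dir, "config.json"))
  })
  invisible(pred)
}

#' File-driven evaluation run
#'
#' Runs the chosen cross-validation protocol on a dataset directory (as
#' written by [write_dataset()]) and writes a JSON summary, the ROC points
#' as TSV, and an ROC plot under `out_dir`.
#'
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @param mode `"5cv"` or `"loocv"`.
#' @param config an [mda_config()].
#' @param n_repeats repeats for `"5cv"`.
#' @param max_folds optional fold subsample for `"loocv"` (approximation).
#' @return the `cv_result`, invisibly.
#' @export
run_evaluate <- function(data_dir, out_dir, mode = c("5cv", "loocv"),
                         config = mda_config(), n_repeats = 5,
                         max_folds = NULL) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- read_dataset(data_dir)
  res <- if (mode == "5cv") {
    five_fold_cv(dataset, config, n_repeats = n_repeats)
  } else {
    global_loocv(dataset, config, max_folds = max_folds)
  }
  readr::write_tsv(res$roc_points, file.path(out_dir, "roc_points.tsv"))
  summary <- list(mode = mode, auc = res$auc,
                  per_repeat_aucs = res$per_repeat_aucs,
                  n_repeats = res$n_repeats,
                  repeat_seeds = if (!is.null(res$n_repeats))
                    res$seed + seq_len(res$n_repeats) - 1L,
                  seed = res$seed,
                  config = unclass(config))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  p <- autoplot(res)
  try(ggplot2::ggsave(file.path(out_dir, "roc.png"), p,
                      width = 5, height = 5, dpi = 150), silent = TRUE)
  invisible(res)
}

write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
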