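#' Tie-aware ROC curve and AUC from scores and labels
#'
#' AUC follows the pairwise Mann-Whitney rule: the fraction of
#' positive-negative pairs where the positive outscores the negative, ties
#' counted half. ROC points come from a sweep over the unique score
#' thresholds, whose trapezoidal area equals that AUC exactly (tied blocks
#' appear as diagonal segments).
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1 or logical), same length.
#' @return a `cv_result` with `auc` and `roc_points`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0L || N == 0L) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  idx <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie block
  tp <- cumsum(l)[idx]
  fp <- cumsum(1L - l)[idx]
  roc <- tibble::tibble(fpr = c(0, fp / N), tpr = c(0, tp / P))

  new_cv_result(auc = auc, roc_points = roc, method = "roc_auc")
}

new_cv_result <- function(auc, roc_points, method,
                          percentiles = NULL, per_repeat_aucs = NULL,
                          n_repeats = NULL, seed = NULL, details = NULL) {
  structure(list(auc = auc, roc_points = roc_points, method = method,
                 percentiles = percentiles,
                 per_repeat_aucs = per_repeat_aucs,
                 n_repeats = n_repeats, seed = seed, details = details),
            class = "cv_result")
}

# Fraction of candidate scores a test score beats, ties counted half.
rank_percentile <- function(score, candidate_scores) {
  (sum(candidate_scores < score) + 0.5 * sum(candidate_scores == score)) /
    length(candidate_scores)
}

# Step ROC curve from per-positive candidate percentiles. A positive with
# percentile u is recovered at false-positive rate 1 - u, so the curve's
# trapezoidal area equals mean(u) -- the same tie-aware AUC as ranking each
# positive against its candidate pool.
roc_from_percentiles <- function(p) {
  u <- sort(unique(p), decreasing = TRUE)
  x <- 1 - u
  y <- vapply(u, function(ui) mean(p >= ui), 0)
  fpr <- c(0, rep(x, each = 2L), 1)
  tpr <- c(0, 0, rep(y[-length(y)], each = 2L), y[length(y)], 1)
  pts <- tibble::tibble(fpr = fpr, tpr = tpr)
  pts[!duplicated(pts), ]
}

#' Global leave-one-out cross-validation of the full pipeline
#'
#' Each verified association is masked in turn, the interaction-profile
#' kernels and fused similarities are rebuilt from the masked matrix (no
#' information leak), the completion model is refitted, and the held-out
#' pair's score is ranked against every pair without verified evidence (the
#' candidate pool, scored by the same fold's model). The AUC is the mean
#' candidate percentile of the held-out pairs.
#'
#' @param dataset an `mda_dataset` (see [generate_dataset()] /
#'   [read_dataset()]).
#' @param config an [mda_config()].
#' @param max_folds optional cap on the number of held-out pairs (a uniform
#'   subsample, seeded by `config$seed`): an approximation for quick runs,
#'   not the full protocol.
#' @param recompute_similarity rebuild kernels per fold (default `TRUE`);
#'   `FALSE` reuses the similarities of the full matrix (faster but leaks
#'   the held-out pair into its own features).
#' @param details keep a per-fold tibble of held-out scores.
#' @return a `cv_result`.
#' @export
global_loocv <- function(dataset, config = mda_config(), max_folds = NULL,
                         recompute_similarity = TRUE, details = FALSE) {
  A <- dataset$assoc
  pos <- which(unclass(A) == 1L, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("need at least 2 known associations", call. = FALSE)
  folds <- seq_len(nrow(pos))
  if (!is.null(max_folds) && max_folds < length(folds)) {
    folds <- with_seed(config$seed, sample(folds, max_folds))
  }
  fixed <- fixed_similarities(dataset, config)
  cand <- which(unclass(A) == 0L)

  res <- purrr::map(folds, function(f) {
    i <- pos[f, 1L]; j <- pos[f, 2L]
    A_tr <- A
    A_tr[i, j] <- 0L
    scores <- fold_scores(A_tr, dataset, config, fixed, recompute_similarity)
    tibble::tibble(disease_id = rownames(A)[i], mirna_id = colnames(A)[j],
                   score = scores[i, j],
                   percentile = rank_percentile(scores[i, j], scores[cand]))
  }) |> purrr::list_rbind()

  new_cv_result(auc = mean(res$percentile),
                roc_points = roc_from_percentiles(res$percentile),
                method = "global_loocv",
                percentiles = res$percentile,
                seed = config$seed,
                details = if (details) res else NULL)
}

#' Repeated five-fold cross-validation of the full pipeline
#'
#' Per repeat, the verified associations are partitioned uniformly at random
#' into five folds; each fold is masked in turn, similarities rebuilt, the
#' model refitted, and the fold's positives ranked against the candidate
#' pool (all pairs without verified evidence, scored by that fold's model).
#' One AUC is computed per repeat over the union of its five folds; the
#' result reports the mean across repeats. Repeat `r` uses seed
#' `seed + r - 1`, so any single repeat is reproducible in isolation.
#'
#' @inheritParams global_loocv
#' @param n_repeats number of random re-partitions.
#' @param seed master seed for the fold partitions (defaults to
#'   `config$seed`).
#' @return a `cv_result` with `per_repeat_aucs`.
#' @export
five_fold_cv <- function(dataset, config = mda_config(), n_repeats = 100,
                         seed = NULL, recompute_similarity = TRUE,
                         details = FALSE) {
  seed <- seed %||% config$seed
  A <- dataset$assoc
  pos <- which(unclass(A) == 1L, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_pos < 5L) stop("need at least 5 known associations", call. = FALSE)
  fixed <- fixed_similarities(dataset, config)
  cand <- which(unclass(A) == 0L)

  all_details <- list()
  per_repeat <- vapply(seq_len(n_repeats), function(rp) {
    fold_of <- with_seed(seed + rp - 1L,
                         sample(rep_len(1:5, n_pos)))
    res <- purrr::map(1:5, function(f) {
      test <- which(fold_of == f)
      A_tr <- A
      A_tr[pos[test, , drop = FALSE]] <- 0L
      scores <- fold_scores(A_tr, dataset, config, fixed, recompute_similarity)
      s <- scores[pos[test, , drop = FALSE]]
      cs <- scores[cand]
      tibble::tibble(repeat_ = rp, fold = f,
                     disease_id = rownames(A)[pos[test, 1L]],
                     mirna_id = colnames(A)[pos[test, 2L]],
                     score = s,
                     percentile = vapply(s, rank_percentile, 0,
                                         candidate_scores = cs))
    }) |> purrr::list_rbind()
    all_details[[rp]] <<- res
    mean(res$percentile)
  }, 0)

  det <- purrr::list_rbind(all_details)
  new_cv_result(auc = mean(per_repeat),
                roc_points = roc_from_percentiles(det$percentile),
                method = "five_fold_cv",
                percentiles = det$percentile,
                per_repeat_aucs = per_repeat,
                n_repeats = n_repeats, seed = seed,
                details = if (details) det else NULL)
}

# Similarities that do not depend on the association matrix and can be
# computed once per CV run: disease semantic similarity and the miRNA
# functional view.
fixed_similarities <- function(dataset, config) {
  ids <- rownames(dataset$assoc)
  DS <- dataset$disease_semantic %||%
    semantic_similarity(dataset$disease_dag, ids, delta = config$delta)
  MF <- dataset$mirna_functional
  stopifnot(identical(rownames(MF), colnames(dataset$assoc)))
  list(DS = DS, MF = MF)
}

# Rebuild association-dependent kernels for one training matrix, fuse, fit,
# and return the full score matrix.
fold_scores <- function(A_tr, dataset, config, fixed, recompute_similarity) {
  if (recompute_similarity || is.null(dataset$.static_sims)) {
    GKD <- gip_similarity(A_tr, "disease", config$gamma_prime_d)
    GKM <- gip_similarity(A_tr, "mirna", config$gamma_prime_m)
    Sd <- snf_fuse(fixed$DS, GKD, k = config$k_neighbors, t_iter = config$t_iter,
                   schedule = config$schedule,
                   symmetrize_each_step = config$symmetrize_each_step)
    Sm <- snf_fuse(fixed$MF, GKM, k = config$k_neighbors, t_iter = config$t_iter,
                   schedule = config$schedule,
                   symmetrize_each_step = config$symmetrize_each_step)
  } else {
    Sd <- dataset$.static_sims$Sd
    Sm <- dataset$.static_sims$Sm
  }
  lam <- effective_lambdas(A_tr, config)
  fit <- fit_imc(A_tr, Sd, Sm, rank = config$rank,
                 lambda1 = lam[1L], lambda2 = lam[2L],
                 tol = config$tol, max_iter = config$max_iter,
                 seed = config$seed)
  predict(fit, Sd, Sm)
}

#' Degree-preserving rewiring of an association matrix
#'
#' Randomizes which diseases connect to which miRNAs while keeping every
#' row and column degree fixed, via repeated checkerboard swaps
#' (`(i1,j1),(i2,j2) -> (i1,j2),(i2,j1)`). Destroys the planted structure,
#' giving a null dataset on which a correct pipeline scores at chance.
#'
#' @param assoc an `assoc_matrix`.
#' @param n_swaps target number of successful swaps (default `10 * nnz`).
#' @param seed integer seed.
#' @return a rewired `assoc_matrix` with identical margins.
#' @export
rewire_associations <- function(assoc, n_swaps = NULL, seed = 1) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  A <- unclass(assoc)
  ones <- which(A == 1L, arr.ind = TRUE)
  nnz <- nrow(ones)
  if (is.null(n_swaps)) n_swaps <- 10L * nnz
  with_seed(seed, {
    done <- 0L
    attempts <- 0L
    while (done < n_swaps && attempts < 100L * n_swaps) {
      attempts <- attempts + 1L
      pick <- sample.int(nnz, 2L)
      i1 <- ones[pick[1L], 1L]; j1 <- ones[pick[1L], 2L]
      i2 <- ones[pick[2L], 1L]; j2 <- ones[pick[2L], 2L]
      if (i1 == i2 || j1 == j2 || A[i1, j2] == 1L || A[i2, j1] == 1L) next
      A[i1, j1] <- 0L; A[i2, j2] <- 0L
      A[i1, j2] <- 1L; A[i2, j1] <- 1L
      ones[pick[1L], ] <- c(i1, j2)
      ones[pick[2L], ] <- c(i2, j1)
      done <- done + 1L
    }
  })
  structure(A, class = class(assoc))
}

with_seed <- function(seed, expr) {
  old <- local_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  expr
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: AUC = %.4f", x$method, x$auc))
  if (!is.null(x$per_repeat_aucs)) {
    cat(sprintf(" (%d repeats, sd %.4f)", x$n_repeats,
                stats::sd(x$per_repeat_aucs)))
  }
  cat("\n")
  invisible(x)
}

#' Tidy the ROC points of a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return tibble with columns `fpr`, `tpr`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$roc_points

#' One-row summary of a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return one-row tibble: method, auc, n_repeats, sd across repeats.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(method = x$method, auc = x$auc,
                 n_repeats = x$n_repeats %||% NA_integer_,
                 auc_sd = if (is.null(x$per_repeat_aucs)) NA_real_
                          else stats::sd(x$per_repeat_aucs))
}

#' ROC curve plot for a cross-validation result
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("%s (AUC = %.4f)", object$method, object$auc)) +
    ggplot2::theme_minimal()
}
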