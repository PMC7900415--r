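#' Regularized inductive matrix completion objective
#'
#' `Phi = 1/2 ||A - Sd U t(V) t(Sm)||_F^2 + lambda1/2 ||U||_F^2 +
#' lambda2/2 ||V||_F^2`. The similarity matrices act as entity feature
#' matrices, so the low-rank factors score any entity through its feature
#' vector alone.
#'
#' @param A association matrix (nd x nm).
#' @param Sd,Sm disease and miRNA feature (similarity) matrices.
#' @param U,V nonnegative factor matrices (nd x r, nm x r).
#' @param lambda1,lambda2 nonnegative regularization weights.
#' @return scalar objective value.
#' @export
imc_objective <- function(A, Sd, Sm, U, V, lambda1 = 1, lambda2 = 1) {
  A <- as.matrix(A); Sd <- as.matrix(Sd); Sm <- as.matrix(Sm)
  check_imc_shapes(A, Sd, Sm, U, V)
  R <- A - Sd %*% U %*% t(V) %*% t(Sm)
  0.5 * sum(R^2) + lambda1 / 2 * sum(U^2) + lambda2 / 2 * sum(V^2)
}

check_imc_shapes <- function(A, Sd, Sm, U, V) {
  nd <- nrow(A); nm <- ncol(A)
  if (nrow(Sd) != nd || ncol(Sd) != nd) stop("Sd must be nd x nd", call. = FALSE)
  if (nrow(Sm) != nm || ncol(Sm) != nm) stop("Sm must be nm x nm", call. = FALSE)
  if (nrow(U) != nd) stop("U must have nd rows", call. = FALSE)
  if (nrow(V) != nm) stop("V must have nm rows", call. = FALSE)
  if (ncol(U) != ncol(V)) stop("U and V must share the rank r", call. = FALSE)
  invisible(TRUE)
}

#' One multiplicative update of the V factor
#'
#' `V <- V * (t(Sm) t(A) Sd U) / (t(Sm) Sm V t(U) t(Sd) Sd U + lambda2 V)`,
#' elementwise, with 1e-12 added to each denominator entry to guard 0/0.
#' Nonnegativity is preserved; entries at exactly zero stay zero.
#'
#' @inheritParams imc_objective
#' @return updated V.
#' @export
imc_update_v <- function(A, Sd, Sm, U, V, lambda2 = 1) {
  A <- as.matrix(A); Sd <- as.matrix(Sd); Sm <- as.matrix(Sm)
  check_imc_shapes(A, Sd, Sm, U, V)
  num <- t(Sm) %*% t(A) %*% Sd %*% U
  den <- crossprod(Sm) %*% V %*% (t(U) %*% crossprod(Sd) %*% U) + lambda2 * V
  V * num / (den + 1e-12)
}

#' One multiplicative update of the U factor
#'
#' `U <- U * (t(Sd) A Sm V) / (t(Sd) Sd U t(V) t(Sm) Sm V + lambda1 U)`,
#' elementwise, with the same 1e-12 denominator guard as [imc_update_v()].
#'
#' @inheritParams imc_objective
#' @return updated U.
#' @export
imc_update_u <- function(A, Sd, Sm, U, V, lambda1 = 1) {
  A <- as.matrix(A); Sd <- as.matrix(Sd); Sm <- as.matrix(Sm)
  check_imc_shapes(A, Sd, Sm, U, V)
  num <- t(Sd) %*% A %*% Sm %*% V
  den <- crossprod(Sd) %*% U %*% (t(V) %*% crossprod(Sm) %*% V) + lambda1 * U
  U * num / (den + 1e-12)
}

#' Fit the nonnegative inductive matrix completion model
#'
#' Alternates the multiplicative updates of V and U (in that order) from a
#' uniform-random nonnegative start until the relative change of the
#' objective drops below `tol` or `max_iter` is reached. The objective is
#' non-increasing along the iterations, which the returned trace records.
#'
#' @param A an `assoc_matrix` (or binary matrix) of known associations.
#' @param Sd,Sm fused disease / miRNA similarity matrices used as features.
#' @param rank target rank r (`r <= min(nd, nm)`); default
#'   `min(50, nd, nm)`.
#' @param lambda1,lambda2 regularization weights (default 1).
#' @param tol relative-objective convergence threshold (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @param seed integer seed for the uniform (0,1) factor initialization.
#' @return an `imc_fit` with elements `U`, `V`, `objective_trace`,
#'   `n_iterations`, the configuration, and the entity ids.
#' @export
fit_imc <- function(A, Sd, Sm, rank = NULL, lambda1 = 1, lambda2 = 1,
                    tol = 1e-6, max_iter = 1000, seed = 1) {
  A <- as.matrix(A); storage.mode(A) <- "double"
  SdM <- as.matrix(Sd); SmM <- as.matrix(Sm)
  nd <- nrow(A); nm <- ncol(A)
  if (is.null(rank)) rank <- min(50L, nd, nm)
  if (rank < 1 || rank > min(nd, nm)) {
    stop("rank must lie in [1, min(nd, nm)]", call. = FALSE)
  }
  stopifnot(tol > 0, lambda1 >= 0, lambda2 >= 0)

  old_seed <- local_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  U <- matrix(runif(nd * rank), nd, rank)
  V <- matrix(runif(nm * rank), nm, rank)

  # Fixed per-run products; each iteration is then O((nd+nm) r^2) plus two
  # small matmuls.
  StS_d <- crossprod(SdM)
  StS_m <- crossprod(SmM)
  M <- t(SdM) %*% A %*% SmM          # nd x nm core data term

  obj <- function(U, V) {
    R <- A - SdM %*% U %*% t(V) %*% t(SmM)
    0.5 * sum(R^2) + lambda1 / 2 * sum(U^2) + lambda2 / 2 * sum(V^2)
  }
  trace <- obj(U, V)
  for (it in seq_len(max_iter)) {
    V <- V * (t(M) %*% U) /
      (StS_m %*% V %*% (t(U) %*% StS_d %*% U) + lambda2 * V + 1e-12)
    U <- U * (M %*% V) /
      (StS_d %*% U %*% (t(V) %*% StS_m %*% V) + lambda1 * U + 1e-12)
    phi <- obj(U, V)
    if (!is.finite(phi)) {
      stop("non-finite objective at iteration ", it, call. = FALSE)
    }
    prev <- trace[length(trace)]
    trace <- c(trace, phi)
    if (abs(prev - phi) / max(prev, 1e-12) < tol) break
  }
  structure(list(U = U, V = V,
                 objective_trace = trace,
                 n_iterations = length(trace) - 1L,
                 disease_ids = rownames(A), mirna_ids = colnames(A),
                 rank = as.integer(rank), lambda1 = lambda1, lambda2 = lambda2,
                 tol = tol, max_iter = max_iter, seed = seed),
            class = "imc_fit")
}

local_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Predicted association scores for all disease-miRNA pairs
#'
#' `S = Sd U t(V) t(Sm)`: entry (i, j) is the feature vector of disease i
#' times the factor product times the feature vector of miRNA j, i.e. the
#' predicted association chance for the pair.
#'
#' @param object an `imc_fit`.
#' @param Sd,Sm the feature matrices used at fit time.
#' @param ... unused.
#' @return a `score_matrix` (numeric matrix with the association dimnames).
#' @export
predict.imc_fit <- function(object, Sd, Sm, ...) {
  S <- as.matrix(Sd) %*% object$U %*% t(object$V) %*% t(as.matrix(Sm))
  dimnames(S) <- list(object$disease_ids, object$mirna_ids)
  structure(S, class = c("score_matrix", class(matrix())))
}

#' Score a disease outside the training rows from its feature vector
#'
#' Inductive prediction: a disease never seen at training time is scored
#' against every miRNA through its similarity (feature) vector alone,
#' `s = sd_new U t(V) t(Sm)`.
#'
#' @param fit an `imc_fit`.
#' @param sd_new nonnegative feature vector over the training diseases.
#' @param Sm miRNA feature matrix used at fit time.
#' @return named numeric vector of scores over miRNAs.
#' @export
predict_novel_disease <- function(fit, sd_new, Sm) {
  stopifnot(inherits(fit, "imc_fit"))
  if (length(sd_new) != nrow(fit$U)) {
    stop("sd_new must have one entry per training disease", call. = FALSE)
  }
  drop(matrix(sd_new, 1) %*% fit$U %*% t(fit$V) %*% t(as.matrix(Sm))) |>
    stats::setNames(fit$mirna_ids)
}

#' @export
print.imc_fit <- function(x, ...) {
  cat(sprintf(
    "<imc_fit> rank %d, %d x %d, %d iterations, objective %.6g -> %.6g\n",
    x$rank, nrow(x$U), nrow(x$V), x$n_iterations,
    x$objective_trace[1L], x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Tidy the objective trace of an IMC fit
#'
#' @param x an `imc_fit`.
#' @param ... unused.
#' @return tibble with columns `iteration` (0 = initialization) and
#'   `objective`.
#' @method tidy imc_fit
#' @export
tidy.imc_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective_trace) - 1L,
                 objective = x$objective_trace)
}

#' One-row summary of an IMC fit
#'
#' @param x an `imc_fit`.
#' @param ... unused.
#' @return one-row tibble: rank, lambdas, iterations run, initial and final
#'   objective, convergence flag.
#' @method glance imc_fit
#' @export
glance.imc_fit <- function(x, ...) {
  tr <- x$objective_trace
  tibble::tibble(rank = x$rank, lambda1 = x$lambda1, lambda2 = x$lambda2,
                 n_iterations = x$n_iterations,
                 objective_initial = tr[1L],
                 objective_final = tr[length(tr)],
                 converged = x$n_iterations < x$max_iter)
}

#' @method as_tibble score_matrix
#' @export
as_tibble.score_matrix <- function(x, ...) {
  tibble::tibble(disease_id = rep(rownames(x), times = ncol(x)),
                 mirna_id = rep(colnames(x), each = nrow(x)),
                 score = as.vector(x)) |>
    dplyr::arrange(match(.data$disease_id, rownames(x)),
                   match(.data$mirna_id, colnames(x)))
}
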