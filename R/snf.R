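#' Full-graph normalized weight matrix
#'
#' Rescales a similarity matrix so each row is a probability vector with half
#' of its mass on the diagonal: off-diagonal entries become
#' `W(i,j) / (2 * sum_{k != i} W(i,k))` and the diagonal is fixed at 1/2.
#' This keeps the diffusion operator numerically stable regardless of the
#' scale of the input similarities. A row with zero off-diagonal mass gets a
#' uniform off-diagonal distribution (with a warning) so the operator stays
#' total on degenerate inputs.
#'
#' @param W a `sim_matrix` or square nonnegative symmetric matrix.
#' @return a row-stochastic matrix (plain matrix, dimnames kept).
#' @export
snf_normalize <- function(W) {
  W <- as.matrix(W)
  n <- nrow(W)
  off <- W
  diag(off) <- 0
  rs <- rowSums(off)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " row(s) with zero off-diagonal similarity; using a",
            " uniform off-diagonal distribution", call. = FALSE)
    off[zero, ] <- 1
    diag(off) <- 0
    rs[zero] <- rowSums(off)[zero]
  }
  P <- off / (2 * rs)
  diag(P) <- 1 / 2
  P
}

#' K-nearest-neighbour local kernel
#'
#' Keeps, for each entity, only the similarities to its `k` most similar
#' neighbours (self excluded) and renormalizes each row to sum to 1; all
#' other entries, including the diagonal, are zero. The local kernel
#' restricts diffusion to each entity's reliable neighbourhood. Neighbour
#' ties are broken by column order for determinism.
#'
#' @param W a `sim_matrix` or square nonnegative symmetric matrix.
#' @param k neighbourhood size, `1 <= k <= n - 1`.
#' @return a sparse-in-effect row-stochastic matrix with at most `k`
#'   nonzeros per row.
#' @export
snf_knn <- function(W, k) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (k < 1 || k > n - 1) stop("k must lie in [1, n-1]", call. = FALSE)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    nb <- cand[order(-W[i, cand], cand)][seq_len(k)]
    w <- W[i, nb]
    if (sum(w) == 0) {
      warning("row ", i, " has all-zero neighbour weights; using uniform",
              call. = FALSE)
      w <- rep(1, k)
    }
    S[i, nb] <- w / sum(w)
  }
  S
}

#' Fuse two similarity views of one entity class by cross-diffusion
#'
#' Similarity network fusion: each view's full kernel is iteratively
#' diffused through the KNN structure of the *other* view
#' (`P1 <- S1 P2 t(S1)`, `P2 <- S2 P1 t(S2)`), so information supported by
#' both networks is reinforced and view-specific noise is damped. The fused
#' similarity is the average of the two kernels after `t_iter` steps; with
#' `t_iter = 0` it reduces exactly to the average of the two normalized
#' views.
#'
#' By default both updates in a step use the kernels from the previous step
#' (the cross-diffusion definition) and each kernel is symmetrized and
#' re-normalized after every step to stop drift from row-stochasticity;
#' `schedule = "sequential"` instead feeds the freshly updated first kernel
#' into the second update, and `symmetrize_each_step = FALSE` disables the
#' stabilization.
#'
#' @param W1,W2 two `sim_matrix` views over the same ids in the same order.
#' @param k KNN neighbourhood size; default `min(20, n - 1)`.
#' @param t_iter number of diffusion steps (default 20).
#' @param schedule `"simultaneous"` (default) or `"sequential"`.
#' @param symmetrize_each_step stabilize each kernel after every step.
#' @return a `sim_matrix` with view `"fused"`.
#' @export
snf_fuse <- function(W1, W2, k = NULL, t_iter = 20,
                     schedule = c("simultaneous", "sequential"),
                     symmetrize_each_step = TRUE) {
  schedule <- match.arg(schedule)
  ids <- rownames(W1)
  if (is.null(ids) || !identical(ids, rownames(W2))) {
    stop("the two views must share identical ids in identical order",
         call. = FALSE)
  }
  n <- nrow(W1)
  if (is.null(k)) k <- min(20L, n - 1L)
  stopifnot(t_iter >= 0)

  P1 <- snf_normalize(W1)
  P2 <- snf_normalize(W2)
  if (t_iter > 0) {
    S1 <- snf_knn(W1, k)
    S2 <- snf_knn(W2, k)
    for (step in seq_len(t_iter)) {
      P1_new <- S1 %*% P2 %*% t(S1)
      P2_new <- S2 %*% (if (schedule == "simultaneous") P1 else P1_new) %*% t(S2)
      P1 <- P1_new
      P2 <- P2_new
      if (symmetrize_each_step) {
        P1 <- renorm_half((P1 + t(P1)) / 2)
        P2 <- renorm_half((P2 + t(P2)) / 2)
      }
    }
  }
  fused <- (P1 + P2) / 2
  if (t_iter == 0) {
    # degenerate no-diffusion case: the exact average of the two normalized
    # views, which is row-stochastic but only approximately symmetric
    dimnames(fused) <- list(ids, ids)
    return(structure(fused, view = "fused",
                     class = c("sim_matrix", class(matrix()))))
  }
  fused <- (fused + t(fused)) / 2
  similarity_matrix(pmax(fused, 0), ids = ids, view = "fused")
}

# Rescale off-diagonal mass of each row to 1/2 and pin the diagonal at 1/2
# (same rule as snf_normalize, applied to an already-diffused kernel).
renorm_half <- function(P) {
  off <- P
  diag(off) <- 0
  rs <- rowSums(off)
  rs[rs == 0] <- 1
  P2 <- off / (2 * rs)
  diag(P2) <- 1 / 2
  P2
}
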