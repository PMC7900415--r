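#' Gaussian interaction-profile kernel bandwidth
#'
#' The kernel bandwidth is the original bandwidth `gamma_prime` normalized
#' by the mean squared norm of the interaction profiles. Profiles are binary,
#' so each squared norm is the exact count of ones in the row.
#'
#' @param profiles binary matrix; one interaction profile per row.
#' @param gamma_prime original bandwidth, > 0 (1 by default, the convention
#'   of the interaction-profile kernel literature).
#' @return normalized bandwidth (scalar).
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  stopifnot(is.matrix(profiles), gamma_prime > 0)
  norms <- rowSums(profiles != 0)
  mean_norm <- mean(norms)
  if (mean_norm == 0) {
    stop("degenerate interaction profiles: every profile is all-zero",
         call. = FALSE)
  }
  gamma_prime / mean_norm
}

#' Gaussian interaction-profile kernel similarity
#'
#' Similarity between two entities is a Gaussian kernel on their binary
#' interaction profiles (rows of the association matrix for diseases,
#' columns for miRNAs): `exp(-gamma * ||K(i) - K(j)||^2)`, with the
#' bandwidth from [gip_bandwidth()]. Identical profiles (including two
#' all-zero profiles) get similarity 1.
#'
#' @param assoc an `assoc_matrix`.
#' @param entity `"disease"` (row profiles) or `"mirna"` (column profiles).
#' @param gamma_prime original bandwidth, > 0.
#' @return a `sim_matrix` with view `"gip"`.
#' @export
gip_similarity <- function(assoc, entity = c("disease", "mirna"),
                           gamma_prime = 1) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  entity <- match.arg(entity)
  P <- if (entity == "disease") unclass(assoc) else t(unclass(assoc))
  storage.mode(P) <- "double"
  gamma <- gip_bandwidth(P, gamma_prime)
  # For binary profiles ||x - y||^2 = ||x||^2 + ||y||^2 - 2 x.y, all integer.
  nrm <- rowSums(P)
  G <- tcrossprod(P)
  D2 <- outer(nrm, nrm, `+`) - 2 * G
  S <- exp(-gamma * D2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  similarity_matrix(S, ids = rownames(P), view = "gip")
}
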