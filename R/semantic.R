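#' Semantic contribution scores of a disease's ancestors
#'
#' Each ancestor term `d` of a disease `D` contributes to `D`'s semantics
#' with a score that decays with distance up the hierarchy: the disease
#' itself contributes 1, and any other ancestor contributes
#' `delta * max(DD(d'))` over its children `d'` that lie on a path back to
#' `D`. Children outside the ancestor closure of `D` carry no contribution
#' because they do not lead back to `D`.
#'
#' @param dag a `disease_dag`.
#' @param disease a term id in `dag`.
#' @param delta semantic contribution factor in (0, 1]; 0.5 by default.
#' @return named numeric vector over the ancestor closure of `disease`.
#' @examples
#' dag <- disease_dag(c("r", "p", "A"),
#'                    tibble::tibble(child = c("A", "p"), parent = c("p", "r")))
#' contribution_scores(dag, "A")  # A = 1, p = 0.5, r = 0.25
#' @export
contribution_scores <- function(dag, disease, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1) {
    stop("delta must lie in (0, 1]", call. = FALSE)
  }
  closure <- ancestor_closure(dag, disease)
  dd <- stats::setNames(numeric(length(closure)), closure)
  # dag$topo lists children before parents, so each ancestor is scored after
  # every child it can inherit from.
  for (t0 in intersect(dag$topo, closure)) {
    if (t0 == disease) {
      dd[[t0]] <- 1
    } else {
      kids <- intersect(dag$children[[t0]], closure)
      dd[[t0]] <- delta * max(dd[kids])
    }
  }
  dd
}

#' Semantic value of a disease
#'
#' The sum of the contribution scores over the disease's ancestor closure;
#' always at least 1 (the disease's own contribution).
#'
#' @inheritParams contribution_scores
#' @return scalar semantic value.
#' @export
semantic_value <- function(dag, disease, delta = 0.5) {
  sum(contribution_scores(dag, disease, delta))
}

#' Disease-disease semantic similarity matrix from a term DAG
#'
#' Two diseases are similar to the extent that they share ancestors, with
#' shared terms weighted by their contribution to each disease:
#' `DS(i, j) = sum over shared ancestors t of (DD_i(t) + DD_j(t))`
#' divided by `DV(i) + DV(j)`. The diagonal is exactly 1 and diseases in
#' disjoint DAG components get similarity 0.
#'
#' @param dag a `disease_dag`.
#' @param diseases ordered ids of the diseases to score (all must be terms).
#' @param delta semantic contribution factor in (0, 1].
#' @return a `sim_matrix` with view `"semantic"`.
#' @export
semantic_similarity <- function(dag, diseases, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  diseases <- as.character(diseases)
  contrib <- lapply(diseases, function(d) contribution_scores(dag, d, delta))
  names(contrib) <- diseases
  dv <- vapply(contrib, sum, 0)
  n <- length(diseases)
  DS <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n)) {
    DS[i, i] <- 1
    if (i < n) for (j in seq.int(i + 1L, n)) {
      shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
      if (length(shared)) {
        DS[i, j] <- DS[j, i] <-
          sum(contrib[[i]][shared] + contrib[[j]][shared]) / (dv[[i]] + dv[[j]])
      }
    }
  }
  similarity_matrix(DS, ids = diseases, view = "semantic")
}
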