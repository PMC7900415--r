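#' Rank predicted scores within each disease
#'
#' @param scores a `score_matrix` (from [predict.imc_fit()]).
#' @param top_k optional: keep only the `top_k` highest-scoring miRNAs per
#'   disease.
#' @return tibble `(disease_id, mirna_id, score, rank)`; rank 1 is the best
#'   candidate per disease, ties broken by miRNA column order.
#' @export
rank_scores <- function(scores, top_k = NULL) {
  stopifnot(inherits(scores, "score_matrix"))
  if (!all(is.finite(scores))) stop("non-finite score entries", call. = FALSE)
  if (!is.null(top_k)) stopifnot(top_k >= 1)
  ranked <- as_tibble(scores) |>
    dplyr::group_by(.data$disease_id) |>
    dplyr::arrange(dplyr::desc(.data$score),
                   match(.data$mirna_id, colnames(scores)),
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (!is.null(top_k)) ranked <- dplyr::slice_head(ranked, n = top_k)
  ranked |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$disease_id, rownames(scores)), .data$rank)
}

#' Write ranked prediction scores to a TSV file
#'
#' @inheritParams rank_scores
#' @param path output path.
#' @export
write_scores <- function(scores, path, top_k = NULL) {
  readr::write_tsv(rank_scores(scores, top_k = top_k), path)
  invisible(path)
}

#' Read a score matrix written by [write_scores()]
#'
#' Only complete (untruncated) score files round-trip to a full matrix.
#' Because score rows are written in rank order, pass `disease_ids` /
#' `mirna_ids` to recover a specific matrix ordering; otherwise ids appear
#' in first-occurrence order.
#'
#' @param path TSV of `(disease_id, mirna_id, score, rank)`.
#' @param disease_ids,mirna_ids optional ordered id vectors for the result.
#' @return a `score_matrix`.
#' @export
read_scores <- function(path, disease_ids = NULL, mirna_ids = NULL) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  d_ids <- disease_ids %||% unique(tab$disease_id)
  m_ids <- mirna_ids %||% unique(tab$mirna_id)
  S <- matrix(NA_real_, length(d_ids), length(m_ids),
              dimnames = list(d_ids, m_ids))
  S[cbind(match(tab$disease_id, d_ids), match(tab$mirna_id, m_ids))] <- tab$score
  if (anyNA(S)) stop("score file does not cover the full matrix: ", path,
                     call. = FALSE)
  structure(S, class = c("score_matrix", class(matrix())))
}
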