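#' Construct a similarity matrix over one entity class
#'
#' A thin validated wrapper around a square symmetric nonnegative matrix with
#' entity ids as dimnames and a `view` attribute naming the similarity source
#' ("semantic", "gip", "functional", "fused", ...).
#'
#' @param values square numeric matrix, nonnegative, symmetric to 1e-10.
#' @param ids entity identifiers (defaults to the matrix rownames).
#' @param view label for the similarity view.
#' @return a `sim_matrix`.
#' @export
similarity_matrix <- function(values, ids = rownames(values), view = "similarity") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square", call. = FALSE)
  if (is.null(ids) || length(ids) != nrow(values)) {
    stop("ids must match the matrix dimension", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate entity ids", call. = FALSE)
  if (any(values < 0)) stop("similarity entries must be nonnegative", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-10) {
    stop("similarity matrix is not symmetric (tolerance 1e-10)", call. = FALSE)
  }
  dimnames(values) <- list(ids, ids)
  structure(values, view = view, class = c("sim_matrix", class(matrix())))
}

sim_view <- function(x) attr(x, "view")

#' Read a similarity matrix from a TSV table with row and column headers
#'
#' Asymmetries up to 1e-8 are accepted silently; larger ones are symmetrized
#' as `(M + t(M)) / 2` with a warning. If `expected_ids` is supplied the rows
#' and columns are permuted to that order, so every matrix in an analysis
#' shares one indexing.
#'
#' @param path TSV file: first column holds row ids, header holds column ids.
#' @param expected_ids optional ordered id vector the matrix must cover.
#' @param view view label recorded on the result.
#' @return a `sim_matrix`.
#' @export
read_similarity <- function(path, expected_ids = NULL, view = "similarity") {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  ids <- as.character(tab[[1L]])
  M <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  if (nrow(M) != ncol(M)) stop("similarity table is not square: ", path, call. = FALSE)
  if (!identical(ids, colnames(M))) {
    stop("row and column ids differ in ", path, call. = FALSE)
  }
  dimnames(M) <- list(ids, ids)
  if (anyNA(M)) stop("non-numeric or missing entries in ", path, call. = FALSE)
  if (any(M < 0)) stop("negative similarity entries in ", path, call. = FALSE)
  asym <- max(abs(M - t(M)))
  if (asym > 1e-8) {
    warning(sprintf("asymmetry %.3g in %s; symmetrizing as (M + t(M))/2", asym, path),
            call. = FALSE)
  }
  M <- (M + t(M)) / 2
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, ids)
    if (length(missing)) {
      stop("similarity file ", path, " is missing ids: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    M <- M[expected_ids, expected_ids, drop = FALSE]
    ids <- expected_ids
  }
  similarity_matrix(M, ids = ids, view = view)
}

#' Write a similarity matrix as a TSV table with headers
#'
#' @param sim a `sim_matrix`.
#' @param path output path.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "sim_matrix"))
  tab <- tibble::as_tibble(unclass(sim), rownames = "id")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("<sim_matrix> view '%s', %d entities\n", sim_view(x), nrow(x)))
  invisible(x)
}
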