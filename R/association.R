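#' Build a binary disease-by-miRNA association matrix from an edge table
#'
#' The association matrix `A` is the binary adjacency of experimentally
#' verified disease--miRNA links: `A[i, j] = 1` iff disease `i` is linked to
#' miRNA `j`. Row and column order follow first occurrence in the edge table
#' and act as the single indexing authority for every downstream matrix.
#'
#' @param edges data frame with columns `disease_id` and `mirna_id` (extra
#'   columns are ignored); one row per verified link, duplicates collapse.
#' @param disease_ids,mirna_ids optional character vectors fixing the row /
#'   column universe and order; must cover every id present in `edges`.
#' @return an `assoc_matrix`: a binary integer matrix with dimnames.
#' @examples
#' edges <- tibble::tibble(disease_id = c("d1", "d1", "d2"),
#'                         mirna_id   = c("m1", "m2", "m2"))
#' association_matrix(edges)
#' @export
association_matrix <- function(edges, disease_ids = NULL, mirna_ids = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("disease_id", "mirna_id") %in% names(edges))) {
    stop("`edges` must have columns disease_id and mirna_id", call. = FALSE)
  }
  dis <- as.character(edges$disease_id)
  mir <- as.character(edges$mirna_id)
  if (nrow(edges) == 0L) stop("empty edge table", call. = FALSE)
  if (any(is.na(dis) | dis == "") || any(is.na(mir) | mir == "")) {
    stop("blank or missing ids in edge table", call. = FALSE)
  }
  if (is.null(disease_ids)) disease_ids <- unique(dis)
  if (is.null(mirna_ids)) mirna_ids <- unique(mir)
  if (anyDuplicated(disease_ids) || anyDuplicated(mirna_ids)) {
    stop("id universe contains duplicates", call. = FALSE)
  }
  missing_d <- setdiff(dis, disease_ids)
  missing_m <- setdiff(mir, mirna_ids)
  if (length(missing_d) || length(missing_m)) {
    stop("edge ids outside the given universe: ",
         paste(c(missing_d, missing_m), collapse = ", "), call. = FALSE)
  }
  A <- matrix(0L, length(disease_ids), length(mirna_ids),
              dimnames = list(disease_ids, mirna_ids))
  A[cbind(match(dis, disease_ids), match(mir, mirna_ids))] <- 1L
  structure(A, class = c("assoc_matrix", class(matrix())))
}

#' Read an association edge list from a TSV file
#'
#' Expects two tab-separated columns (`disease_id`, `mirna_id`), an optional
#' header naming them, and `#`-prefixed comment lines which are ignored.
#'
#' @param path file path.
#' @inheritParams association_matrix
#' @return an `assoc_matrix` (see [association_matrix()]).
#' @export
read_associations <- function(path, disease_ids = NULL, mirna_ids = NULL) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- seq_along(keep)[keep]
  if (length(lines) == 0L) stop("empty association file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed association line ", line_no[bad[1L]], " in ", path,
         " (expected 2 tab-separated fields)", call. = FALSE)
  }
  d <- vapply(parts, `[[`, "", 1L)
  m <- vapply(parts, `[[`, "", 2L)
  if (identical(tolower(d[1L]), "disease_id")) {
    d <- d[-1L]
    m <- m[-1L]
    if (length(d) == 0L) stop("association file has a header but no rows", call. = FALSE)
  }
  association_matrix(tibble::tibble(disease_id = d, mirna_id = m),
                     disease_ids = disease_ids, mirna_ids = mirna_ids)
}

#' Write an association matrix back to its edge-list form
#'
#' @param assoc an `assoc_matrix`.
#' @param path output TSV path.
#' @export
write_associations <- function(assoc, path) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  idx <- which(assoc == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  readr::write_tsv(tibble::tibble(disease_id = rownames(assoc)[idx[, 1L]],
                                  mirna_id   = colnames(assoc)[idx[, 2L]]),
                   path)
  invisible(path)
}

#' @method as_tibble assoc_matrix
#' @export
as_tibble.assoc_matrix <- function(x, ...) {
  idx <- which(x == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(disease_id = rownames(x)[idx[, 1L]],
                 mirna_id   = colnames(x)[idx[, 2L]])
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d diseases x %d miRNAs, %d known associations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}
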