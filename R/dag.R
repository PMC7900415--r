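#' Construct a disease term DAG from a child-to-parent edge table
#'
#' Diseases are described by their position in a term hierarchy (MeSH-style
#' descriptors): the DAG of a disease consists of the term itself plus all of
#' its ancestors, connected by child-to-parent edges. Acyclicity is verified
#' at construction.
#'
#' @param terms character vector of term ids.
#' @param edges data frame with columns `child` and `parent`, both drawn from
#'   `terms`; duplicate edges collapse.
#' @return a `disease_dag` with elements `terms`, `edges` (tibble),
#'   `parents` and `children` (named lists), and `roots`.
#' @export
disease_dag <- function(terms, edges) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term ids", call. = FALSE)
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("child", "parent") %in% names(edges))) {
    stop("`edges` must have columns child and parent", call. = FALSE)
  }
  child <- as.character(edges$child %||% character())
  parent <- as.character(edges$parent %||% character())
  unknown <- setdiff(c(child, parent), terms)
  if (length(unknown)) {
    stop("edge references unknown terms: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- !duplicated(paste(child, parent, sep = "\r"))
  child <- child[keep]
  parent <- parent[keep]
  if (any(child == parent)) stop("self-loop edge detected", call. = FALSE)

  parents <- split(parent, factor(child, levels = terms))
  children <- split(child, factor(parent, levels = terms))

  # Kahn's algorithm over child -> parent edges both orders the terms
  # (children before parents) and proves acyclicity.
  n_par <- lengths(parents)
  n_child <- lengths(children)
  order <- character(0)
  queue <- terms[n_child == 0L]
  remaining <- n_child
  while (length(queue)) {
    t0 <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, t0)
    for (p in parents[[t0]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) != length(terms)) {
    cyc <- setdiff(terms, order)
    stop("cycle detected in term DAG involving: ",
         paste(head(cyc, 10L), collapse = " -> "), call. = FALSE)
  }
  structure(list(terms = terms,
                 edges = tibble::tibble(child = child, parent = parent),
                 parents = parents,
                 children = children,
                 roots = terms[n_par == 0L],
                 topo = order),
            class = "disease_dag")
}

#' Read a term DAG from a term list and a child-parent edge list
#'
#' @param term_path TSV/plain file with one term id per line (optional
#'   header `term`); `#` comments ignored.
#' @param edge_path TSV with two columns `child`, `parent` (optional header).
#' @return a `disease_dag`.
#' @export
read_dag <- function(term_path, edge_path) {
  tl <- readr::read_lines(term_path)
  tl <- trimws(tl[!grepl("^\\s*#", tl) & nzchar(trimws(tl))])
  if (length(tl) && identical(tolower(tl[1L]), "term")) tl <- tl[-1L]
  if (!length(tl)) stop("empty term file: ", term_path, call. = FALSE)

  el <- readr::read_lines(edge_path)
  el <- el[!grepl("^\\s*#", el) & nzchar(trimws(el))]
  parts <- strsplit(el, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed DAG edge line ", bad[1L], " in ", edge_path, call. = FALSE)
  }
  child <- vapply(parts, `[[`, "", 1L)
  parent <- vapply(parts, `[[`, "", 2L)
  if (length(child) && identical(tolower(child[1L]), "child")) {
    child <- child[-1L]
    parent <- parent[-1L]
  }
  disease_dag(tl, tibble::tibble(child = child, parent = parent))
}

#' Write a term DAG to the two-file form read by [read_dag()]
#'
#' @param dag a `disease_dag`.
#' @param term_path,edge_path output paths.
#' @export
write_dag <- function(dag, term_path, edge_path) {
  stopifnot(inherits(dag, "disease_dag"))
  readr::write_lines(c("term", dag$terms), term_path)
  readr::write_tsv(dag$edges, edge_path)
  invisible(c(term_path, edge_path))
}

#' Ancestor closure of a term
#'
#' Returns the term itself plus every term reachable through child-to-parent
#' edges -- the node set of the disease's own DAG.
#'
#' @param dag a `disease_dag`.
#' @param term a term id.
#' @return character vector of term ids (unordered set).
#' @export
ancestor_closure <- function(dag, term) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!term %in% dag$terms) stop("unknown term: ", term, call. = FALSE)
  seen <- character(0)
  stack <- term
  while (length(stack)) {
    t0 <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (t0 %in% seen) next
    seen <- c(seen, t0)
    stack <- c(stack, setdiff(dag$parents[[t0]], seen))
  }
  seen
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> %d terms, %d edges, %d root(s)\n",
              length(x$terms), nrow(x$edges), length(x$roots)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
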