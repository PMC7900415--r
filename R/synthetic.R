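#' Generate a random layered term DAG
#'
#' One root; the remaining terms are spread over the layers below it and
#' each non-root term receives one or two parents drawn uniformly from the
#' layer directly above -- acyclic by construction, every term's ancestor
#' closure contains the root.
#'
#' @param n_terms number of terms (`>= n_layers`).
#' @param n_layers number of layers (`>= 1`); with one layer the DAG is a
#'   single root and no edges.
#' @param seed integer seed.
#' @param prefix id prefix for the generated terms.
#' @return a `disease_dag`.
#' @export
generate_dag <- function(n_terms, n_layers = 4, seed = 1, prefix = "T") {
  stopifnot(n_layers >= 1, n_terms >= n_layers)
  terms <- sprintf("%s%03d", prefix, seq_len(n_terms))
  if (n_terms == 1L || n_layers == 1L) {
    return(disease_dag(terms[1L],
                       tibble::tibble(child = character(), parent = character())))
  }
  with_seed(seed, {
    layer <- c(1L, sort(sample(rep_len(2:n_layers, n_terms - 1L))))
    child <- character(0)
    parent <- character(0)
    for (t0 in which(layer > 1L)) {
      above <- terms[layer == layer[t0] - 1L]
      n_par <- min(sample(1:2, 1L), length(above))
      for (p in sample(above, n_par)) {
        child <- c(child, terms[t0])
        parent <- c(parent, p)
      }
    }
    disease_dag(terms, tibble::tibble(child = child, parent = parent))
  })
}

#' Generate a synthetic miRNA-disease dataset with planted structure
#'
#' Emulates the three inputs the pipeline consumes. Nonnegative factors
#' `U*` (nd x rank) and `V*` (nm x rank) are sparse gamma draws: each entry
#' is Gamma(shape 2, scale 1) with probability `activity` and exactly zero
#' otherwise (at least one active component per row), and every factor row
#' is then normalized to unit sum. Each disease and each miRNA therefore
#' participates in a subset of the latent processes with equal total
#' propensity: association signal lives in *which* latent processes a pair
#' shares, not in how many links an entity has, so a degree-preserving
#' rewire of `A` destroys all predictable structure. The latent score
#' matrix `L = U* t(V*)` (rescaled to `[0, 1]`) gives each pair's
#' propensity, and `A` is sampled Bernoulli per cell with the success
#' probabilities calibrated so the expected fraction of ones equals
#' `density`. The miRNA functional similarity is the cosine
#' similarity of the `V*` rows corrupted by a symmetric uniform perturbation
#' of magnitude `noise` (clipped to `[0, 1]`, unit diagonal). The disease
#' term DAG places diseases with similar `U*` rows under the same synthetic
#' ancestor terms, so semantic similarity tracks the planted structure.
#'
#' @param nd,nm numbers of diseases and miRNAs.
#' @param rank planted rank (`<= min(nd, nm)`).
#' @param density target expected fraction of ones in `A`, in (0, 1).
#' @param noise similarity corruption magnitude, `>= 0`.
#' @param activity probability that a factor entry is active (nonzero).
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param second_parent_prob probability a disease term gets a second
#'   ancestor cluster in the DAG.
#' @return an `mda_dataset`: list with `assoc`, `mirna_functional`,
#'   `disease_dag`, `truth` (planted `U`, `V`, latent `L`, Bernoulli
#'   probabilities) and `seed`.
#' @export
generate_dataset <- function(nd = 60, nm = 80, rank = 3, density = 0.06,
                             noise = 0.1, seed = 1, activity = 0.25,
                             second_parent_prob = 0.2) {
  stopifnot(rank >= 1, rank <= min(nd, nm), density > 0, density < 1,
            noise >= 0, activity > 0, activity <= 1)
  disease_ids <- sprintf("D%03d", seq_len(nd))
  mirna_ids <- sprintf("M%03d", seq_len(nm))

  with_seed(seed, {
    U <- matrix(rgamma(nd * rank, shape = 2, scale = 1), nd, rank) *
      activity_mask(nd, rank, activity)
    V <- matrix(rgamma(nm * rank, shape = 2, scale = 1), nm, rank) *
      activity_mask(nm, rank, activity)
    U <- U / rowSums(U)
    V <- V / rowSums(V)
    L <- U %*% t(V)
    L <- L / max(L)
    prob <- pmin(density / mean(L) * L, 1)
    A <- matrix(rbinom(nd * nm, 1L, prob), nd, nm)
    # Empty interaction profiles would break the kernel bandwidth, so any
    # all-zero row/column is redrawn (its cells only, same probabilities);
    # low-propensity profiles make a whole-matrix redraw hopeless.
    for (attempt in 1:10) {
      er <- which(rowSums(A) == 0L)
      ec <- which(colSums(A) == 0L)
      if (!length(er) && !length(ec)) break
      warning("resampling ", length(er), " empty row(s) and ", length(ec),
              " empty column(s)", call. = FALSE)
      for (i in er) A[i, ] <- rbinom(nm, 1L, prob[i, ])
      for (j in ec) A[, j] <- rbinom(nd, 1L, prob[, j])
    }
    if (any(rowSums(A) == 0L) || any(colSums(A) == 0L)) {
      stop("density too low: could not sample a matrix without empty profiles",
           call. = FALSE)
    }
    dimnames(A) <- list(disease_ids, mirna_ids)
    assoc <- structure(A, class = c("assoc_matrix", class(matrix())))

    # miRNA functional view: cosine similarity of planted factor rows plus
    # symmetric noise in similarity space.
    Vn <- V / sqrt(rowSums(V^2))
    MF <- tcrossprod(Vn)
    if (noise > 0) {
      E <- matrix(runif(nm * nm, -noise, noise), nm, nm)
      E <- (E + t(E)) / 2
      MF <- MF + E
    }
    MF <- pmin(pmax(MF, 0), 1)
    diag(MF) <- 1
    mf <- similarity_matrix(MF, ids = mirna_ids, view = "functional")

    dag <- disease_cluster_dag(U, disease_ids, second_parent_prob)

    structure(list(assoc = assoc, mirna_functional = mf, disease_dag = dag,
                   truth = list(U = U, V = V, L = L, prob = prob),
                   seed = seed),
              class = "mda_dataset")
  })
}

# Sparse activity pattern with at least one active component per row.
activity_mask <- function(n, rank, activity) {
  m <- matrix(rbinom(n * rank, 1L, activity), n, rank)
  for (i in which(rowSums(m) == 0L)) m[i, sample.int(rank, 1L)] <- 1L
  m
}

# Multilevel DAG over synthetic ancestor terms, mirroring the depth of a
# real descriptor hierarchy: the dendrogram of the planted disease factor
# rows (Ward linkage) is cut at 2, 4, 8, ... clusters; each cut level
# becomes a layer of ancestor terms, each cluster term hangs under the
# coarser cluster holding most of its members, and diseases attach to their
# finest cluster (occasionally to a second one). Diseases with similar
# factor rows therefore share deep ancestors and get high semantic
# similarity.
disease_cluster_dag <- function(U, disease_ids, second_parent_prob) {
  nd <- nrow(U)
  hc <- stats::hclust(stats::dist(U), method = "ward.D2")
  sizes <- 2^(1:5)
  sizes <- sizes[sizes <= max(2L, nd %/% 2L)]
  root <- "ROOT"
  terms <- root
  child <- character(0)
  parent <- character(0)
  assign_prev <- rep(root, nd)
  level_ids <- NULL
  for (li in seq_along(sizes)) {
    cl <- stats::cutree(hc, k = sizes[li])
    level_ids <- sprintf("L%d_%02d", li, seq_len(sizes[li]))
    for (c0 in seq_len(sizes[li])) {
      members <- which(cl == c0)
      par <- names(which.max(table(assign_prev[members])))
      terms <- c(terms, level_ids[c0])
      child <- c(child, level_ids[c0])
      parent <- c(parent, par)
    }
    assign_prev <- level_ids[cl]
  }
  finest <- assign_prev
  for (i in seq_len(nd)) {
    child <- c(child, disease_ids[i])
    parent <- c(parent, finest[i])
    others <- setdiff(unique(finest), finest[i])
    if (length(others) && runif(1) < second_parent_prob) {
      child <- c(child, disease_ids[i])
      parent <- c(parent, sample(others, 1L))
    }
  }
  disease_dag(c(terms, disease_ids),
              tibble::tibble(child = child, parent = parent))
}

#' Write a dataset to the plain-text formats the readers consume
#'
#' Produces `associations.tsv`, `mirna_functional.tsv`, `dag_terms.tsv` and
#' `dag_edges.tsv` under `dir`, so a pipeline run on files is identical to a
#' run on the in-memory dataset. The planted truth is not written.
#'
#' @param dataset an `mda_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mda_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_associations(dataset$assoc, file.path(dir, "associations.tsv"))
  write_similarity(dataset$mirna_functional,
                   file.path(dir, "mirna_functional.tsv"))
  write_dag(dataset$disease_dag, file.path(dir, "dag_terms.tsv"),
            file.path(dir, "dag_edges.tsv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory holding `associations.tsv`, `mirna_functional.tsv`,
#'   `dag_terms.tsv`, `dag_edges.tsv`.
#' @return an `mda_dataset` (with no planted truth).
#' @export
read_dataset <- function(dir) {
  # the functional similarity fixes the canonical miRNA order (the edge list
  # encounters miRNAs in ranking order, not registry order)
  mf <- read_similarity(file.path(dir, "mirna_functional.tsv"),
                        view = "functional")
  assoc <- read_associations(file.path(dir, "associations.tsv"),
                             mirna_ids = rownames(mf))
  dag <- read_dag(file.path(dir, "dag_terms.tsv"),
                  file.path(dir, "dag_edges.tsv"))
  structure(list(assoc = assoc, mirna_functional = mf, disease_dag = dag,
                 truth = NULL, seed = NA_integer_),
            class = "mda_dataset")
}

#' @export
print.mda_dataset <- function(x, ...) {
  cat(sprintf("<mda_dataset> %d diseases x %d miRNAs, %d associations, seed %s\n",
              nrow(x$assoc), ncol(x$assoc), sum(x$assoc),
              format(x$seed)))
  invisible(x)
}
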