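# Small builders shared across tests.

toy_edges <- function() {
  tibble::tibble(disease_id = c("d1", "d1", "d2"),
                 mirna_id   = c("m1", "m2", "m2"))
}

chain_dag <- function() {
  # A -> p -> r
  disease_dag(c("r", "p", "A"),
              tibble::tibble(child = c("A", "p"), parent = c("p", "r")))
}

shared_root_dag <- function() {
  # A -> r <- B
  disease_dag(c("r", "A", "B"),
              tibble::tibble(child = c("A", "B"), parent = c("r", "r")))
}

diamond_dag <- function() {
  # A -> {b, c} -> r
  disease_dag(c("r", "b", "c", "A"),
              tibble::tibble(child = c("A", "A", "b", "c"),
                             parent = c("b", "c", "r", "r")))
}

random_sim <- function(n, seed, ids = sprintf("e%02d", seq_len(n))) {
  set.seed(seed)
  M <- matrix(runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  similarity_matrix(M, ids = ids, view = "test")
}

random_assoc <- function(nd, nm, seed, p = 0.2) {
  set.seed(seed)
  repeat {
    A <- matrix(rbinom(nd * nm, 1L, p), nd, nm,
                dimnames = list(sprintf("d%02d", seq_len(nd)),
                                sprintf("m%02d", seq_len(nm))))
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) break
  }
  structure(A, class = c("assoc_matrix", class(matrix())))
}

small_dataset <- function(seed = 42, nd = 30, nm = 40) {
  suppressWarnings(generate_dataset(nd = nd, nm = nm, rank = 3,
                                    density = 0.1, noise = 0.1, seed = seed))
}

# Memoization-free recursive contribution score: the independent oracle for
# the semantic similarity recursion.
brute_contribution <- function(dag, D, d, delta) {
  if (d == D) return(1)
  closure <- ancestor_closure(dag, D)
  kids <- intersect(dag$children[[d]], closure)
  if (!length(kids)) return(NA_real_)
  delta * max(vapply(kids, function(k) brute_contribution(dag, D, k, delta), 0))
}

brute_semantic_pair <- function(dag, di, dj, delta) {
  Ti <- ancestor_closure(dag, di)
  Tj <- ancestor_closure(dag, dj)
  ddi <- vapply(Ti, function(t0) brute_contribution(dag, di, t0, delta), 0)
  ddj <- vapply(Tj, function(t0) brute_contribution(dag, dj, t0, delta), 0)
  shared <- intersect(Ti, Tj)
  if (!length(shared)) return(0)
  sum(ddi[shared] + ddj[shared]) / (sum(ddi) + sum(ddj))
}

# All-pairs Mann-Whitney count with half credit for ties: the AUC oracle.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
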