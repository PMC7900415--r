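test_that("association edge lists transcribe to the binary matrix", {
  A <- association_matrix(toy_edges())
  expect_identical(dim(A), c(2L, 2L))
  expect_identical(rownames(A), c("d1", "d2"))
  expect_identical(colnames(A), c("m1", "m2"))
  expect_equal(unclass(A)[, ], matrix(c(1L, 0L, 1L, 1L), 2, 2,
               dimnames = list(c("d1", "d2"), c("m1", "m2"))))

  # duplicate rows collapse to a single 1
  dup <- dplyr::bind_rows(toy_edges(), toy_edges()[1, ])
  expect_equal(unclass(association_matrix(dup)), unclass(A))
})

test_that("association files round-trip and reject malformed input", {
  set.seed(1)
  edges <- tibble::tibble(
    disease_id = sprintf("d%02d", sample(30, 200, replace = TRUE)),
    mirna_id   = sprintf("m%02d", sample(40, 200, replace = TRUE))) |>
    dplyr::distinct()
  A <- association_matrix(edges)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_associations(A, path)
  A2 <- read_associations(path, disease_ids = rownames(A),
                          mirna_ids = colnames(A))
  expect_identical(unclass(A2), unclass(A))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\tm1", "only_one_field"), bad)
  expect_error(read_associations(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_associations(empty), "empty")
})

test_that("similarity tables read, permute to expected ids, and symmetrize", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tm1\tm2", "m1\t1\t0.3", "m2\t0.3\t1"), path)
  S <- read_similarity(path)
  expect_s3_class(S, "sim_matrix")
  expect_equal(S[1, 2], 0.3)

  Sp <- read_similarity(path, expected_ids = c("m2", "m1"))
  expect_identical(rownames(Sp), c("m2", "m1"))
  expect_equal(Sp["m2", "m1"], 0.3)

  asym <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tm1\tm2", "m1\t1\t0.30", "m2\t0.31\t1"), asym)
  expect_warning(S3 <- read_similarity(asym), "symmetrizing")
  expect_equal(S3[1, 2], 0.305)
  expect_equal(S3[2, 1], 0.305)

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tm1\tm2", "m1\t1\t-0.1", "m2\t-0.1\t1"), neg)
  expect_error(read_similarity(neg), "negative")

  expect_error(read_similarity(path, expected_ids = c("m1", "m2", "m9")),
               "m9")
})

test_that("similarity matrices round-trip through write + read", {
  S <- random_sim(7, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(S, path)
  S2 <- read_similarity(path, expected_ids = rownames(S))
  expect_identical(rownames(S2), rownames(S))
  expect_lt(max(abs(unclass(S2) - unclass(S))), 1e-12)
})

test_that("DAG files parse, and cycles or unknown terms are errors", {
  tpath <- withr::local_tempfile(fileext = ".tsv")
  epath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term", "r", "a"), tpath)
  writeLines("a\tr", epath)
  dag <- read_dag(tpath, epath)
  expect_setequal(ancestor_closure(dag, "a"), c("a", "r"))
  expect_identical(dag$roots, "r")

  writeLines(c("a\tb", "b\ta"), epath)
  writeLines(c("term", "a", "b"), tpath)
  expect_error(read_dag(tpath, epath), "cycle")

  writeLines("a\tzz", epath)
  expect_error(read_dag(tpath, epath), "unknown")
})

test_that("score files rank per disease with deterministic ties and top_k", {
  S <- structure(matrix(c(0.2, 0.9, 0.5), 1, 3,
                        dimnames = list("d1", c("m1", "m2", "m3"))),
                 class = c("score_matrix", class(matrix())))
  rk <- rank_scores(S)
  expect_identical(rk$rank[match(c("m1", "m2", "m3"), rk$mirna_id)],
                   c(3L, 1L, 2L))

  tie <- structure(matrix(c(0.5, 0.5), 1, 2,
                          dimnames = list("d1", c("m1", "m2"))),
                   class = c("score_matrix", class(matrix())))
  rk2 <- rank_scores(tie)
  expect_identical(rk2$mirna_id[rk2$rank == 1L], "m1")

  wide <- structure(matrix(runif(5), 1, 5,
                           dimnames = list("d1", sprintf("m%d", 1:5))),
                    class = c("score_matrix", class(matrix())))
  expect_identical(nrow(rank_scores(wide, top_k = 2)), 2L)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(wide, path)
  back <- read_scores(path, disease_ids = rownames(wide),
                      mirna_ids = colnames(wide))
  expect_lt(max(abs(unclass(back) - unclass(wide))), 1e-12)

  bad <- wide
  bad[1, 1] <- NaN
  expect_error(write_scores(bad, path), "non-finite")
})
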