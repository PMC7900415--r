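test_that("ROC/AUC handles separation, ties, and random scores", {
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0))$auc, 0.5)
  set.seed(1)
  r <- roc_auc(runif(10000), rbinom(10000, 1, 0.5))
  expect_lt(abs(r$auc - 0.5), 0.02)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "one positive and one negative")
})

test_that("AUC equals the all-pairs count and pROC agrees", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-14)
  }
  set.seed(99)
  scores <- runif(500)
  labels <- rbinom(500, 1, 0.3)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("ROC points are a valid curve whose area is the AUC", {
  check_curve <- function(r) {
    pts <- r$roc_points
    expect_equal(pts$fpr[1], 0)
    expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1)
    expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    expect_equal(trapezoid(pts$fpr, pts$tpr), r$auc, tolerance = 1e-10)
  }
  set.seed(2)
  check_curve(roc_auc(runif(200), rbinom(200, 1, 0.3)))
  check_curve(roc_auc(sample(1:5, 200, TRUE), rbinom(200, 1, 0.3)))
  # percentile-based curve used by the CV protocols
  p <- runif(57)
  pts <- snfimc:::roc_from_percentiles(p)
  expect_equal(trapezoid(pts$fpr, pts$tpr), mean(p), tolerance = 1e-10)
})

test_that("AUC is invariant under strictly increasing transformations", {
  set.seed(3)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, 0.4)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(scores^3 + 5 * scores, labels)$auc, a0)
})

test_that("degree-preserving rewiring keeps every margin", {
  A <- random_assoc(15, 20, seed = 4)
  B <- rewire_associations(A, seed = 9)
  expect_identical(rowSums(unclass(B)), rowSums(unclass(A)))
  expect_identical(colSums(unclass(B)), colSums(unclass(A)))
  expect_identical(sort(unique(as.vector(unclass(B)))), c(0L, 1L))
  expect_false(identical(unclass(B), unclass(A)))
})

test_that("five-fold CV partitions every positive exactly once per repeat", {
  ds <- small_dataset()
  cfg <- mda_config(seed = 1, t_iter = 3, max_iter = 60)
  res <- five_fold_cv(ds, cfg, n_repeats = 2, seed = 5, details = TRUE)
  pos <- as_tibble(ds$assoc)
  for (rp in 1:2) {
    det <- res$details[res$details$repeat_ == rp, ]
    expect_identical(nrow(det), nrow(pos))
    expect_identical(
      nrow(dplyr::distinct(det, disease_id, mirna_id)), nrow(pos))
  }
  expect_length(res$per_repeat_aucs, 2)
  expect_equal(res$auc, mean(res$per_repeat_aucs))
})

test_that("cross-validation is deterministic and leaves the input intact", {
  ds <- small_dataset()
  A_before <- unclass(ds$assoc)
  cfg <- mda_config(seed = 1, t_iter = 3, max_iter = 60)
  r1 <- five_fold_cv(ds, cfg, n_repeats = 1, seed = 5)
  r2 <- five_fold_cv(ds, cfg, n_repeats = 1, seed = 5)
  expect_identical(r1$auc, r2$auc)
  expect_identical(unclass(ds$assoc), A_before)

  l1 <- global_loocv(ds, cfg, max_folds = 8)
  l2 <- global_loocv(ds, cfg, max_folds = 8)
  expect_identical(l1$auc, l2$auc)
  expect_identical(unclass(ds$assoc), A_before)
})

test_that("fold models are fitted on the masked matrix only (no leak)", {
  ds <- small_dataset()
  cfg <- mda_config(seed = 1, t_iter = 3, max_iter = 60)
  res <- five_fold_cv(ds, cfg, n_repeats = 1, seed = 5, details = TRUE)

  # reproduce fold 1 by hand: identical partition seed, identical masking
  A <- ds$assoc
  pos <- which(unclass(A) == 1L, arr.ind = TRUE)
  set.seed(5)
  fold_of <- sample(rep_len(1:5, nrow(pos)))
  test <- which(fold_of == 1)
  A_tr <- A
  A_tr[pos[test, , drop = FALSE]] <- 0L
  expect_identical(sum(A_tr), sum(A) - length(test))

  DS <- semantic_similarity(ds$disease_dag, rownames(A), delta = cfg$delta)
  GKD <- gip_similarity(A_tr, "disease")
  GKM <- gip_similarity(A_tr, "mirna")
  Sd <- snf_fuse(DS, GKD, t_iter = cfg$t_iter)
  Sm <- snf_fuse(ds$mirna_functional, GKM, t_iter = cfg$t_iter)
  fit <- fit_imc(A_tr, Sd, Sm, lambda1 = 1, lambda2 = 1,
                 max_iter = cfg$max_iter, seed = cfg$seed)
  S <- predict(fit, Sd, Sm)

  det <- res$details[res$details$fold == 1, ]
  manual <- S[cbind(match(det$disease_id, rownames(A)),
                    match(det$mirna_id, colnames(A)))]
  expect_equal(det$score, unname(manual), tolerance = 1e-12)

  # the masked positives really are absent from the profiles the kernels saw
  expect_true(all(unclass(A_tr)[pos[test, , drop = FALSE]] == 0L))
})

test_that("cv_result tidiers and autoplot work", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0))
  expect_identical(names(tidy(r)), c("fpr", "tpr"))
  expect_identical(glance(r)$method, "roc_auc")
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
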