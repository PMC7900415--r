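test_that("objective matches its closed forms at special points", {
  A <- random_assoc(6, 8, seed = 1)
  Sd <- diag(6)
  Sm <- diag(8)
  U0 <- matrix(0, 6, 3)
  V0 <- matrix(0, 8, 3)
  expect_equal(imc_objective(A, Sd, Sm, U0, V0, 1, 1), sum(A) / 2)

  set.seed(2)
  U <- matrix(runif(6 * 3), 6, 3)
  V <- matrix(runif(8 * 3), 8, 3)
  Ahat <- U %*% t(V)
  expect_equal(imc_objective(Ahat, Sd, Sm, U, V, 0, 0), 0, tolerance = 1e-12)

  # linear in lambda1 through the ||U||^2 term
  phi1 <- imc_objective(A, Sd, Sm, U, V, 1, 1)
  phi2 <- imc_objective(A, Sd, Sm, U, V, 2, 1)
  expect_equal(phi2 - phi1, sum(U^2) / 2, tolerance = 1e-12)

  expect_error(imc_objective(A, diag(5), Sm, U, V), "Sd")
})

test_that("multiplicative updates have the expected fixed points", {
  A <- random_assoc(6, 8, seed = 3)
  Sd <- diag(6)
  Sm <- diag(8)
  set.seed(4)
  U <- matrix(runif(6 * 3), 6, 3)
  V <- matrix(runif(8 * 3), 8, 3)

  expect_equal(imc_update_v(A, Sd, Sm, U, matrix(0, 8, 3), 1),
               matrix(0, 8, 3))
  expect_equal(imc_update_u(A, Sd, Sm, matrix(0, 6, 3), V, 1),
               matrix(0, 6, 3))

  # at an exact factorization with no regularization the ratio is 1
  Ahat <- U %*% t(V)
  expect_equal(imc_update_v(Ahat, Sd, Sm, U, V, 0), V, tolerance = 1e-9)
  expect_equal(imc_update_u(Ahat, Sd, Sm, U, V, 0), U, tolerance = 1e-9)
})

test_that("a single update never increases the objective", {
  for (seed in 1:30) {
    set.seed(seed)
    A <- matrix(rbinom(48, 1, 0.3), 8, 6)
    Sd <- crossprod(matrix(runif(64), 8, 8)) / 8
    Sm <- crossprod(matrix(runif(36), 6, 6)) / 6
    U <- matrix(runif(8 * 3), 8, 3)
    V <- matrix(runif(6 * 3), 6, 3)
    lam <- runif(1, 0, 2)
    phi0 <- imc_objective(A, Sd, Sm, U, V, lam, lam)
    V1 <- imc_update_v(A, Sd, Sm, U, V, lam)
    phi1 <- imc_objective(A, Sd, Sm, U, V1, lam, lam)
    expect_lte(phi1, phi0 * (1 + 1e-9))
    U1 <- imc_update_u(A, Sd, Sm, U, V1, lam)
    phi2 <- imc_objective(A, Sd, Sm, U1, V1, lam, lam)
    expect_lte(phi2, phi1 * (1 + 1e-9))
  }
})

test_that("the solver is deterministic and monotone with a full trace", {
  A <- random_assoc(10, 12, seed = 5)
  Sd <- unclass(random_sim(10, seed = 6))
  Sm <- unclass(random_sim(12, seed = 7))
  fit1 <- fit_imc(A, Sd, Sm, rank = 4, seed = 11, max_iter = 200)
  fit2 <- fit_imc(A, Sd, Sm, rank = 4, seed = 11, max_iter = 200)
  expect_identical(fit1$U, fit2$U)
  expect_identical(fit1$V, fit2$V)

  tr <- fit1$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * pmax(head(tr, -1), 1)))
  expect_identical(fit1$n_iterations, length(tr) - 1L)
})

test_that("zero associations with regularization shrink the factors", {
  A0 <- matrix(0, 6, 7)
  fit <- fit_imc(A0, diag(6), diag(7), rank = 2, lambda1 = 1, lambda2 = 1,
                 seed = 1, max_iter = 100)
  tr <- fit$objective_trace
  expect_lt(tr[length(tr)], tr[1])
  expect_lt(sum(fit$U^2) + sum(fit$V^2), 1e-4)
})

test_that("an exact-rank planted instance is recovered", {
  set.seed(7)
  U0 <- matrix(runif(30 * 3), 30, 3)
  V0 <- matrix(runif(40 * 3), 40, 3)
  Ap <- U0 %*% t(V0)
  fit <- fit_imc(Ap, diag(30), diag(40), rank = 3, lambda1 = 0, lambda2 = 0,
                 seed = 42, max_iter = 2000)
  resid <- sqrt(sum((Ap - fit$U %*% t(fit$V))^2) / sum(Ap^2))
  expect_lt(resid, 0.05)

  fit1 <- fit_imc(Ap, diag(30), diag(40), rank = 1, lambda1 = 0, lambda2 = 0,
                  seed = 42, max_iter = 2000)
  expect_lt(fit$objective_trace[length(fit$objective_trace)],
            fit1$objective_trace[length(fit1$objective_trace)])
})

test_that("scoring matches the per-pair double loop and training features", {
  A <- random_assoc(7, 9, seed = 8)
  Sd <- unclass(random_sim(7, seed = 9, ids = rownames(A)))
  Sm <- unclass(random_sim(9, seed = 10, ids = colnames(A)))
  fit <- fit_imc(A, Sd, Sm, rank = 3, seed = 2, max_iter = 50)
  S <- predict(fit, Sd, Sm)
  for (i in 1:7) for (j in 1:9) {
    expect_equal(S[i, j],
                 unname(drop(Sd[i, , drop = FALSE] %*% fit$U %*% t(fit$V) %*%
                               Sm[j, ])),
                 tolerance = 1e-12)
  }
  # identity features degenerate to the plain factor product
  fitI <- fit_imc(A, diag(7), diag(9), rank = 3, seed = 2, max_iter = 20)
  expect_equal(unclass(predict(fitI, diag(7), diag(9))),
               fitI$U %*% t(fitI$V), ignore_attr = TRUE)
  expect_true(all(unclass(S) >= 0))
})

test_that("novel-disease scoring is the linear feature extension", {
  A <- random_assoc(6, 8, seed = 11)
  Sd <- unclass(random_sim(6, seed = 12, ids = rownames(A)))
  Sm <- unclass(random_sim(8, seed = 13, ids = colnames(A)))
  fit <- fit_imc(A, Sd, Sm, rank = 2, seed = 3, max_iter = 30)
  S <- predict(fit, Sd, Sm)

  # the indicator of a training disease reproduces its score row
  e2 <- as.numeric(seq_len(6) == 2)
  expect_equal(unname(predict_novel_disease(fit, Sd[2, ], Sm)),
               unname(S[2, ]), tolerance = 1e-12)
  expect_equal(unname(predict_novel_disease(fit, e2 %*% Sd, Sm)),
               unname(S[2, ]), tolerance = 1e-12)
  expect_equal(unname(predict_novel_disease(fit, rep(0, 6), Sm)),
               rep(0, 8))
  avg <- (Sd[1, ] + Sd[3, ]) / 2
  expect_equal(unname(predict_novel_disease(fit, avg, Sm)),
               unname((S[1, ] + S[3, ]) / 2), tolerance = 1e-12)
  expect_error(predict_novel_disease(fit, rep(1, 5), Sm), "one entry")
})

test_that("tidy and glance summarize a fit", {
  A <- random_assoc(5, 6, seed = 14)
  fit <- fit_imc(A, diag(5), diag(6), rank = 2, seed = 1, max_iter = 25)
  td <- tidy(fit)
  expect_identical(names(td), c("iteration", "objective"))
  expect_identical(td$iteration[1], 0L)
  g <- glance(fit)
  expect_identical(g$rank, 2L)
  expect_lte(g$objective_final, g$objective_initial)
})
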