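test_that("rmse_percent matches its definition", {
  expect_equal(rmse_percent(c(0, 1), c(0, 1)), 0)
  expect_equal(rmse_percent(c(0, 1), c(0.5, 0.5)), 50)
  set.seed(51)
  y <- array(rnorm(24), c(4, 3, 2)); yh <- y + array(rnorm(24), c(4, 3, 2))
  acc <- 0
  for (i in seq_along(y)) acc <- acc + (y[i] - yh[i])^2
  expect_equal(rmse_percent(y, yh), 100 * sqrt(acc / 24))
  expect_error(rmse_percent(1:3, 1:4), "length")
})

test_that("coef_distance is a scale/sign-invariant pseudometric", {
  B <- matrix(rnorm(12), 3)
  expect_equal(coef_distance(B, B), 0)
  expect_equal(coef_distance(B, -3 * B), 0)
  expect_equal(coef_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_error(coef_distance(B, 0 * B), "zero")
  set.seed(52)
  for (i in 1:20) {
    A <- rnorm(6); Bv <- rnorm(6); Cv <- rnorm(6)
    expect_equal(coef_distance(A, Bv), coef_distance(Bv, A))
    expect_lte(coef_distance(A, Cv),
               coef_distance(A, Bv) + coef_distance(Bv, Cv) + 1e-12)
  }
  # signed variant distinguishes a sign flip
  expect_equal(coef_distance(B, -B, signed = TRUE), 2)
  expect_equal(coef_distance(B, B, signed = TRUE), 0)
})

test_that("welch_test reproduces the reference comparison-table cells", {
  w <- welch_test(0.16, 0.01, 10, 0.15, 0.01, 10)
  expect_equal(w$t, 2.236, tolerance = 1e-3)
  expect_equal(w$df, 18)
  expect_equal(round(w$t_crit, 2), 2.88)
  expect_false(w$significant)
  w <- welch_test(3.1, 0.2, 10, 2.8, 0.1, 10)
  expect_equal(w$t, 4.243, tolerance = 1e-3)
  expect_equal(w$df, 13.24, tolerance = 0.01)
  expect_equal(round(w$t_crit, 2), 3.00)
  expect_true(w$significant)
  w0 <- welch_test(1, 0.1, 10, 1, 0.1, 10)
  expect_equal(w0$t, 0)
  expect_false(w0$significant)
  expect_error(welch_test(1, 0, 10, 1, 0.1, 10), "positive")
  expect_error(welch_test(1, 0.1, 1, 1, 0.1, 10), "exceed")
})

test_that("correlation_report returns per-coordinate Pearson r", {
  set.seed(53)
  Y <- matrix(rnorm(40), 20)
  expect_equal(correlation_report(Y, Y), c(1, 1))
  expect_equal(correlation_report(Y[, 1], -Y[, 1]), -1)
  Yh <- Y + matrix(rnorm(40), 20)
  expect_equal(correlation_report(Y, Yh),
               c(cor(Y[, 1], Yh[, 1]), cor(Y[, 2], Yh[, 2])))
})

test_that("modality influence profiles are separable and sum to 100", {
  a <- c(1, 2, 3); b <- c(4, 5)
  mi <- modality_influence(outer_prod(list(a, b)))
  expect_equal(mi[[1]], 100 * a / sum(a))
  expect_equal(mi[[2]], 100 * b / sum(b))
  set.seed(54)
  B <- array(rnorm(24), c(2, 3, 4))
  mi <- modality_influence(B)
  for (p in mi) {
    expect_true(all(p >= 0))
    expect_equal(sum(p), 100, tolerance = 1e-9)
  }
  # permuting an axis permutes its profile
  perm <- c(3, 1, 2)
  Bp <- B[, perm, ]
  expect_equal(modality_influence(Bp)[[2]], mi[[2]][perm])
})

test_that("cross-validated factor selection finds the exact rank", {
  set.seed(55)
  y <- rnorm(60); a <- rnorm(4); b <- rnorm(3)
  X <- outer_prod(list(y, a, b))  # rank-1, noiseless
  f <- select_factors_cv(X, y, "npls", 1:3, k_folds = 5, seed = 1)
  expect_equal(f, 1L)
  f2 <- select_factors_cv(X, y, "npls", 1:3, k_folds = 5, seed = 1)
  expect_identical(f, f2)
  expect_true(f %in% 1:3)
})

test_that("the convergence scenario emits coherent distance traces", {
  rep <- run_scenario("convergence",
                      list(n = 160, block_size = 20, noise_percent = 0,
                           n_realizations = 2, nfactors = 2), seed = 1)
  expect_equal(dim(rep$d_true), c(2L, 8L))
  expect_equal(dim(rep$d_successive), c(2L, 7L))
  expect_true(all(is.finite(rep$d_true)))
  # noiseless: estimates converge onto the truth quickly
  expect_true(all(rep$d_true[, 5:8] < 0.2))
  df <- write_report_csv(rep, tempfile(fileext = ".csv"))
  expect_equal(names(df), c("scenario", "realization", "iteration",
                            "d_successive", "d_true"))
})

test_that("forgetting speeds up adaptation after an abrupt reversal", {
  cfg <- list(n = 1000, block_size = 50, change_point = 500,
              noise_percent = 100, n_realizations = 2, nfactors = 3)
  rep_fast <- run_scenario("adaptivity", c(cfg, lambda = 0.9), seed = 2)
  rep_slow <- run_scenario("adaptivity", c(cfg, lambda = 1), seed = 2)
  ci <- rep_fast$change_iteration
  at10 <- ci + 10
  expect_lt(mean(rep_fast$d_new_truth[, at10]),
            mean(rep_slow$d_new_truth[, at10]))
})

test_that("the comparison scenario emits the full table schema", {
  rep <- run_scenario("table1",
                      list(n = 200, block_size = 25,
                           noise_levels = c(100, 500),
                           n_realizations = 2, F_grid = 1:2, k_folds = 3),
                      seed = 1)
  expect_equal(length(rep$rows), 2L)
  for (row in rep$rows) {
    expect_equal(colnames(row$rmse), c("rnpls", "npls", "inpls", "upls"))
    expect_equal(nrow(row$rmse), 2L)
    expect_true(all(is.finite(row$rmse)))
    expect_equal(names(row$welch), c("npls", "inpls", "upls"))
  }
  df <- write_report_csv(rep, tempfile(fileext = ".csv"))
  expect_equal(names(df), c("scenario", "noise", "method", "nfactors",
                            "realization", "rmse"))
  expect_equal(nrow(df), 2 * 4 * 2)
})
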