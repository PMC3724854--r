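test_that("orthonormalize_scores produces an exact triangular factorization", {
  Q0 <- qr.Q(qr(matrix(rnorm(20 * 3), 20)))
  on <- orthonormalize_scores(Q0)
  expect_equal(on$T_orth, Q0, tolerance = 1e-10)
  expect_equal(on$G, diag(3), tolerance = 1e-10)
  set.seed(21)
  T <- matrix(rnorm(20 * 5), 20)
  on <- orthonormalize_scores(T)
  expect_lt(max(abs(crossprod(on$T_orth) - diag(5))), 1e-10)
  expect_lt(max(abs(on$T_orth %*% on$G - T)), 1e-10)
  expect_true(all(diag(on$G) > 0))
  expect_true(all(abs(on$G[lower.tri(on$G)]) < 1e-12))
  Tdup <- cbind(T[, 1], T[, 1], T[, 2])
  expect_error(orthonormalize_scores(Tdup), "rank deficient")
})

test_that("absorb_residual satisfies the reconstruction identity", {
  set.seed(22)
  T <- matrix(rnorm(15 * 3), 15)
  on <- orthonormalize_scores(T)
  P <- matrix(rnorm(8 * 3), 8)
  E <- matrix(rnorm(15 * 8), 15)
  ab <- absorb_residual(on$T_orth, on$G, P, E)
  expect_lt(max(abs(tcrossprod(T, P) + E -
                    (tcrossprod(on$T_orth, ab$P_bar) + ab$E_bar))), 1e-10)
  expect_lt(max(abs(crossprod(on$T_orth, ab$E_bar))), 1e-10)
  # E already orthogonal to the scores: loadings rotate, residual unchanged
  Eo <- E - on$T_orth %*% crossprod(on$T_orth, E)
  ab2 <- absorb_residual(on$T_orth, on$G, P, Eo)
  expect_equal(ab2$E_bar, Eo, tolerance = 1e-10)
  expect_equal(t(ab2$P_bar), on$G %*% t(P), tolerance = 1e-10)
  ab3 <- absorb_residual(on$T_orth, on$G, P, matrix(0, 15, 8))
  expect_equal(ab3$E_bar, matrix(0, 15, 8))
  expect_error(absorb_residual(on$T_orth, on$G, P, matrix(0, 14, 8)),
               "shapes")
})

test_that("initialization matches the batch fit on the first block", {
  d <- make_exact_factor_data(30, 5, 4, 3, seed = 23)
  st <- rnpls_init(d$X, d$Y, 3)
  expect_lt(st$diagnostics$resid_ratio, 1e-8)
  mb <- fit_npls(d$X, d$Y, 3)
  expect_equal(predict(st, d$X), predict(mb, d$X), tolerance = 1e-8)
  expect_error(rnpls_init(d$X, d$Y, 3, lambda = 0), "lambda")
  expect_error(rnpls_init(d$X, d$Y, 3, lambda = 1.2), "lambda")
  expect_error(suppressWarnings(rnpls_init(d$X, d$Y, 12)),
               "rank|factors")
})

test_that("recursive updates reproduce the batch fit on exact-rank data", {
  d <- make_exact_factor_data(48, 5, 4, 3, seed = 24)
  mb <- fit_npls(d$X, d$Y, 3)
  Bb <- coef_tensor(mb)
  for (nb in c(2, 4, 8)) {
    st <- run_rnpls_blocks(block_split(d$X, d$Y, nb), 3)
    expect_lt(rel_fro(coef_tensor(st), Bb), 1e-6)
    expect_equal(tensor_dim(st$L_X)[1], 3L)  # memory bound
    expect_equal(st$n_seen, 48)
  }
  # tensor-output variant
  dt <- make_exact_factor_data(40, 4, 3, 2, seed = 25, y_shape = 2L)
  mbt <- fit_npls(dt$X, dt$Y, 2)
  stt <- run_rnpls_blocks(block_split(dt$X, dt$Y, 4), 2)
  expect_lt(rel_fro(coef_tensor(stt), coef_tensor(mbt)), 1e-6)
})

test_that("feeding the same information twice leaves the direction unchanged", {
  d <- make_exact_factor_data(24, 4, 3, 2, seed = 26)
  st <- rnpls_init(d$X, d$Y, 2)
  B1 <- coef_tensor(st)
  st2 <- rnpls_update(st, d$X, d$Y)
  expect_lt(coef_distance(coef_tensor(st2), B1), 1e-8)
})

test_that("order-2 recursive NPLS coincides with matrix recursive PLS", {
  set.seed(27)
  X <- matrix(rnorm(40 * 6), 40)
  y <- as.vector(X %*% rnorm(6))
  blocks <- list(list(X = X[1:20, ], Y = y[1:20]),
                 list(X = X[21:40, ], Y = y[21:40]))
  st <- run_rnpls_blocks(blocks, 3)
  mr <- fit_rpls(blocks, 3)
  expect_lt(max(abs(coef_tensor(st) - coef_tensor(mr))), 1e-8)
  Xn <- matrix(rnorm(5 * 6), 5)
  expect_equal(predict(st, Xn), predict(mr, Xn), tolerance = 1e-8)
})

test_that("prediction from a state is linear and delegates to its model", {
  d <- make_exact_factor_data(30, 4, 3, 2, seed = 28)
  st <- run_rnpls_blocks(block_split(d$X, d$Y, 3), 2)
  expect_equal(predict(st, array(0, c(4, 4, 3))), rep(0, 4))
  x1 <- rand_tensor(c(6, 4, 3), 1); x2 <- rand_tensor(c(6, 4, 3), 2)
  expect_equal(predict(st, x1 + 0.5 * x2),
               predict(st, x1) + 0.5 * predict(st, x2), tolerance = 1e-10)
  expect_equal(predict(st, x1), predict(st$model, x1))
  expect_equal(coef_tensor(st), coef_tensor(st$model))
})

test_that("orthogonality certificates hold after every noisy update", {
  set.seed(29)
  n <- 90
  X <- array(rnorm(n * 5 * 4), c(n, 5, 4))
  y <- rnorm(n)
  blocks <- block_split(X, y, 6)
  st <- rnpls_init(blocks[[1]]$X, blocks[[1]]$Y, 3, lambda = 0.9)
  for (b in blocks[-1]) {
    st <- rnpls_update(st, b$X, b$Y)
    expect_lt(st$diagnostics$orth_error, 1e-10)
    expect_lt(st$diagnostics$x_resid_orth, 1e-10)
    expect_lt(st$diagnostics$y_resid_orth, 1e-10)
  }
})

test_that("forgetting lets the model track a class reversal", {
  sp <- list(n_bumps = 3L, width = c(0.6, 1.5), background_scale = 5)
  cfg <- sim_config(600, 100, seed = 31, change_point = 300,
                    template_spec = sp)
  ds <- sample_dataset(cfg)
  blocks <- block_split(ds$X, ds$y, 12)  # 50-sample blocks
  st <- rnpls_init(blocks[[1]]$X, blocks[[1]]$Y, 3, lambda = 0.8,
                   quiet = TRUE)
  for (b in blocks[2:12]) st <- rnpls_update(st, b$X, b$Y, quiet = TRUE)
  B <- coef_tensor(st)
  d_new <- coef_distance(B, -ds$B_true, signed = TRUE)
  d_old <- coef_distance(B, ds$B_true, signed = TRUE)
  expect_lt(d_new, d_old)
})

test_that("states serialize losslessly through the tensor container", {
  d <- make_exact_factor_data(30, 4, 3, 2, seed = 32)
  blocks <- block_split(d$X, d$Y, 3)
  st <- run_rnpls_blocks(blocks[1:2], 2)
  path <- tempfile(fileext = ".rnpls")
  save_rnpls_state(st, path)
  st2 <- load_rnpls_state(path)
  Xn <- rand_tensor(c(6, 4, 3), 3)
  expect_equal(predict(st2, Xn), predict(st, Xn))
  expect_equal(st2$lambda, st$lambda)
  expect_equal(st2$n_seen, st$n_seen)
  # resuming the stream after a round trip matches the uninterrupted run
  st_cont <- rnpls_update(st, blocks[[3]]$X, blocks[[3]]$Y)
  st_resumed <- rnpls_update(st2, blocks[[3]]$X, blocks[[3]]$Y)
  expect_equal(predict(st_resumed, Xn), predict(st_cont, Xn),
               tolerance = 1e-10)
})
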