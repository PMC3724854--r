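test_that("unfold follows the pinned column ordering and matches brute force", {
  t3 <- array(1:8, c(2, 2, 2))  # element (i,j,k) = i + 2(j-1) + 4(k-1)
  expect_equal(unfold(t3, 1), matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2))
  for (dims in list(c(3, 2, 2), c(2, 3, 4), c(2, 2, 2, 3))) {
    x <- rand_tensor(dims, seed = sum(dims))
    for (m in seq_along(dims))
      expect_equal(unfold(x, m), unfold_bruteforce(x, m))
  }
  expect_error(unfold(t3, 4), "mode")
  expect_error(unfold(t3, 0), "mode")
})

test_that("fold inverts unfold for every mode up to order 4", {
  for (dims in list(5L, c(4, 3), c(3, 4, 2), c(2, 3, 2, 4))) {
    x <- rand_tensor(dims, seed = prod(dims))
    for (m in seq_along(dims))
      expect_identical(fold(unfold(x, m), m, dims), x)
  }
})

test_that("vectorize, outer_prod and unfold conventions are consistent", {
  expect_equal(vectorize(outer_prod(list(c(1, 2), c(3, 4)))), c(3, 6, 4, 8))
  v <- c(2, -1, 3)
  expect_equal(vectorize(v), v)
  x <- rand_tensor(c(3, 2, 4), 7)
  expect_equal(sqrt(sum(vectorize(x)^2)), sqrt(sum(x^2)))
  expect_equal(outer_prod(list(c(1, 2), c(3, 4))),
               matrix(c(3, 6, 4, 8), 2))
  expect_equal(outer_prod(list(c(5))), 5)
  vs <- list(rnorm(3), rnorm(4), rnorm(2))
  expect_equal(sqrt(sum(outer_prod(vs)^2)),
               prod(vapply(vs, function(v) sqrt(sum(v^2)), 1)))
  # rank-1 identity: unfold(t o w1 o w2, 1) = t %*% t(vectorize(w1 o w2))
  t <- rnorm(5); w1 <- rnorm(3); w2 <- rnorm(2)
  rk1 <- outer_prod(list(t, w1, w2))
  expect_equal(unfold(rk1, 1),
               tcrossprod(t, vectorize(outer_prod(list(w1, w2)))))
  expect_error(outer_prod(list()), "non-empty")
})

test_that("sample_contract sums weighted first-mode slices", {
  x <- rand_tensor(c(4, 3, 2), 11)
  e1 <- c(1, 0, 0, 0)
  expect_equal(sample_contract(x, e1), array(x[1, , ], c(3, 2)))
  expect_equal(sample_contract(x, rep(0, 4)), array(0, c(3, 2)))
  Xm <- matrix(rnorm(12), 4)
  u <- rnorm(4)
  expect_equal(sample_contract(Xm, u), as.vector(crossprod(Xm, u)))
  expect_error(sample_contract(x, rnorm(3)), "first-mode")
})

test_that("rank_one_approx recovers exact rank-1 tensors and singular pairs", {
  z <- 2 * outer_prod(list(c(1, 0), c(0, 1)))
  r <- rank_one_approx(z)
  expect_equal(r$ws[[1]], c(1, 0))
  expect_equal(r$ws[[2]], c(0, 1))
  expect_equal(r$scale, 2)
  set.seed(42)
  zm <- matrix(rnorm(9), 3)
  r <- rank_one_approx(zm)
  sv <- svd(zm)
  s1 <- sign(sv$u[which.max(abs(sv$u[, 1])), 1])
  expect_equal(r$ws[[1]], s1 * sv$u[, 1], tolerance = 1e-8)
  expect_equal(r$scale * r$ws[[2]][1] * r$ws[[1]][1],
               sv$d[1] * sv$u[1, 1] * sv$v[1, 1], tolerance = 1e-8)
  # degenerate tie: identity input still yields a valid unit pair
  r <- rank_one_approx(diag(2))
  expect_equal(sum(r$ws[[1]]^2), 1, tolerance = 1e-12)
  expect_equal(sum(r$ws[[2]]^2), 1, tolerance = 1e-12)
  expect_error(rank_one_approx(array(0, c(2, 2))), "zero")
})

test_that("rank_one_approx on order-3 tensors matches a multi-start search", {
  set.seed(3)
  z <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  fit <- rank_one_approx(z)
  resid <- function(ws, s)
    sqrt(sum((z - s * outer_prod(ws))^2))
  r0 <- resid(fit$ws, fit$scale)
  # multi-start ALS oracle (independent little implementation)
  best <- Inf
  for (rep in 1:20) {
    ws <- lapply(dim(z), function(J) { v <- rnorm(J); v / sqrt(sum(v^2)) })
    for (it in 1:200) {
      for (k in 1:3) {
        v <- 1
        for (m in setdiff(1:3, k)) v <- kronecker(ws[[m]], v)
        # build contraction directly from definition
        wk <- numeric(dim(z)[k])
        for (i in seq_len(dim(z)[k])) {
          slice <- switch(k, z[i, , ], z[, i, ], z[, , i])
          rest <- outer(ws[[setdiff(1:3, k)[1]]], ws[[setdiff(1:3, k)[2]]])
          wk[i] <- sum(slice * rest)
        }
        ws[[k]] <- wk / sqrt(sum(wk^2))
        sc <- sqrt(sum(wk^2))
      }
    }
    best <- min(best, resid(ws, sc))
  }
  expect_lte(r0, best + 1e-6)
  # rank-one fit never beats the data norm and removes something
  expect_lt(r0, sqrt(sum(z^2)))
})
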