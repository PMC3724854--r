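# Comparison methods: ordinary PLS with orthonormal scores, Qin's blockwise
# recursive PLS, unfolded PLS for tensor data, and the multi-pass blockwise
# iterative NPLS.

#' Ordinary PLS with orthonormal scores
#'
#' Iterative (NIPALS-style) partial least squares for matrix input and
#' vector/matrix output, with score deflation and scores re-normalized to be
#' orthonormal (\code{t(T) \%*\% T = I}).  Uncentered by default so that the
#' fitted model is a purely linear map; set \code{center = TRUE} to subtract
#' column means (stored and re-applied at prediction).
#'
#' @param X numeric matrix, n by p.
#' @param Y numeric vector (length n) or matrix (n by q).
#' @param nfactors number of factors, at most \code{min(n, p)}.
#' @param center logical; subtract column means of X and Y before fitting.
#' @param tol inner-loop tolerance on the relative change of the score.
#' @param max_iter maximum inner-loop iterations per factor.
#' @return Object of class \code{"pls_model"} with weights \code{W},
#'   loadings \code{P}, orthonormal scores \code{T}, latent coefficients
#'   \code{B_latent} and optional means.
#' @export
fit_pls <- function(X, Y, nfactors, center = FALSE, tol = 1e-10,
                    max_iter = 200L) {
  X <- as.matrix(X)
  scalar_y <- is.null(dim(Y))
  Ym <- if (scalar_y) matrix(as.vector(Y), ncol = 1L) else as.matrix(Y)
  check_tensor(X); check_tensor(Ym)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Ym) != n) stop("X and Y sample counts differ", call. = FALSE)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (nfactors < 1L || nfactors > min(n, p))
    stop("'nfactors' must be in 1..min(n, p)", call. = FALSE)
  x_means <- NULL; y_means <- NULL
  if (center) {
    x_means <- colMeans(X); y_means <- colMeans(Ym)
    X <- sweep(X, 2L, x_means); Ym <- sweep(Ym, 2L, y_means)
  }
  Ex <- X; Ey <- Ym
  W <- matrix(0, p, 0L); P <- matrix(0, p, 0L); Tm <- matrix(0, n, 0L)
  t_norms <- numeric(0)
  for (f in seq_len(nfactors)) {
    if (sqrt(sum(Ex^2)) < 1e-12 * max(1, sqrt(sum(X^2)))) {
      warning("X residual numerically zero after ", f - 1L,
              " factors; stopping early")
      break
    }
    u <- Ey[, 1L]
    if (sum(u^2) == 0) u <- rep(1, n)
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- as.vector(crossprod(Ex, u))
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("degenerate weight vector", call. = FALSE)
      w <- w / nw
      tf <- as.vector(Ex %*% w)
      if (ncol(Ey) == 1L) { u <- Ey[, 1L] }
      else {
        q <- as.vector(crossprod(Ey, tf))
        q <- q / sqrt(sum(q^2))
        u <- as.vector(Ey %*% q)
      }
      if (sqrt(sum((tf - t_old)^2)) <= tol * max(sqrt(sum(tf^2)), 1e-300))
        break
      t_old <- tf
    }
    nt <- sqrt(sum(tf^2))
    if (nt < 1e-12) { warning("zero score at factor ", f); break }
    tf <- tf / nt                       # orthonormal score
    pf <- as.vector(crossprod(Ex, tf))  # loading: Ex ~ tf %*% t(pf)
    Ex <- Ex - tcrossprod(tf, pf)
    cf <- as.vector(crossprod(Ey, tf))
    Ey <- Ey - tcrossprod(tf, cf)
    W <- cbind(W, w); P <- cbind(P, pf); Tm <- cbind(Tm, tf)
    t_norms <- c(t_norms, nt)
  }
  if (ncol(Tm) == 0L) stop("no factors extracted", call. = FALSE)
  dimnames(Tm) <- NULL; dimnames(W) <- NULL; dimnames(P) <- NULL
  B_latent <- crossprod(Tm, Ym)         # lstsq with orthonormal T
  structure(list(W = W, P = P, T = Tm, B_latent = B_latent,
                 t_norms = t_norms,
                 nfactors = ncol(Tm), p = p, q = ncol(Ym),
                 scalar_y = scalar_y, x_means = x_means, y_means = y_means),
            class = "pls_model")
}

pls_scores <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != model$p)
    stop("Xnew has wrong number of columns", call. = FALSE)
  if (!is.null(model$x_means)) Xnew <- sweep(Xnew, 2L, model$x_means)
  E <- Xnew
  Tm <- matrix(0, nrow(Xnew), model$nfactors)
  for (f in seq_len(model$nfactors)) {
    tf <- as.vector(E %*% model$W[, f]) / model$t_norms[f]
    Tm[, f] <- tf
    E <- E - tcrossprod(tf, model$P[, f])
  }
  Tm
}

#' Predict from an ordinary PLS model
#'
#' @param object fitted \code{"pls_model"}.
#' @param Xnew matrix of new inputs.
#' @param ... unused.
#' @return Vector (scalar output) or matrix of predictions.
#' @export
predict.pls_model <- function(object, Xnew, ...) {
  Yh <- pls_scores(object, Xnew) %*% object$B_latent
  if (!is.null(object$y_means)) Yh <- sweep(Yh, 2L, -object$y_means)
  if (object$scalar_y) as.vector(Yh) else Yh
}

#' @rdname coef_tensor
#' @export
coef_tensor.pls_model <- function(object, ...) {
  B <- pls_scores_basis(object) %*% object$B_latent
  if (object$scalar_y) as.vector(B) else B
}

pls_scores_basis <- function(model) {
  E <- diag(model$p)
  Tm <- matrix(0, model$p, model$nfactors)
  for (f in seq_len(model$nfactors)) {
    tf <- as.vector(E %*% model$W[, f]) / model$t_norms[f]
    Tm[, f] <- tf
    E <- E - tcrossprod(tf, model$P[, f])
  }
  Tm
}

#' Blockwise recursive PLS (Qin's algorithm)
#'
#' Fits ordinary PLS to the first block, then for every further block stacks
#' the forgetting-weighted loadings (input side) and projected outputs
#' (output side) on top of the new data and refits.  With \code{lambda = 1}
#' and data of exact factor structure this equals the batch fit on the
#' concatenated blocks.
#'
#' @param blocks list of \code{list(X = , Y = )} pairs (matrices/vectors).
#' @param nfactors number of factors.
#' @param lambda forgetting factor in \code{(0, 1]}.
#' @param ... passed to [fit_pls()].
#' @return \code{"pls_model"} fitted on the final compressed data.
#' @export
fit_rpls <- function(blocks, nfactors, lambda = 1, ...) {
  if (!is.list(blocks) || length(blocks) == 0L)
    stop("'blocks' must be a non-empty list of (X, Y) pairs", call. = FALSE)
  if (lambda <= 0 || lambda > 1)
    stop("'lambda' must be in (0, 1]", call. = FALSE)
  state <- NULL
  for (b in blocks) {
    Xb <- as.matrix(b$X)
    Yb <- if (is.null(dim(b$Y))) matrix(as.vector(b$Y), ncol = 1L)
          else as.matrix(b$Y)
    if (is.null(state)) {
      Xs <- Xb; Ys <- Yb
    } else {
      Xs <- rbind(lambda * t(state$P_comp), Xb)
      Ys <- rbind(lambda * state$C_comp, Yb)
    }
    m <- fit_pls(Xs, Ys, nfactors, ...)
    if (m$nfactors < nfactors)
      stop("rank collapse during recursive update; reduce 'nfactors' or ",
           "enlarge the block", call. = FALSE)
    # compress: absorb residual into loadings (scores already orthonormal)
    E <- Xs - tcrossprod(m$T, m$P)
    ab <- absorb_residual(m$T, diag(nfactors), m$P, E)
    state <- list(P_comp = ab$P_bar, C_comp = crossprod(m$T, Ys), model = m)
  }
  m <- state$model
  m$scalar_y <- is.null(dim(blocks[[1L]]$Y))
  m
}

#' Unfolded PLS for tensor observations
#'
#' Unfolds the input and output tensors along the sample mode and delegates
#' to [fit_pls()]; the coefficient tensor is refolded to
#' \code{c(x_shape, y_shape)}.
#'
#' @param X input observation tensor (samples in mode 1).
#' @param Y output observation tensor or vector.
#' @param nfactors number of factors.
#' @param ... passed to [fit_pls()].
#' @return Object of class \code{c("upls_model", "pls_model")} carrying the
#'   tensor shapes.
#' @export
fit_upls <- function(X, Y, nfactors, ...) {
  m <- fit_pls(unfold(X, 1L), y_unfold(Y), nfactors, ...)
  m$x_shape <- tensor_dim(X)[-1L]
  m$y_shape <- y_shape_of(Y)
  m$scalar_y <- is.null(dim(Y))
  class(m) <- c("upls_model", "pls_model")
  m
}

#' @export
predict.upls_model <- function(object, Xnew, ...) {
  Yh <- pls_scores(object, unfold(Xnew, 1L)) %*% object$B_latent
  if (!is.null(object$y_means)) Yh <- sweep(Yh, 2L, -object$y_means)
  fold_output(Yh, object$y_shape, nrow(Yh))
}

#' @rdname coef_tensor
#' @export
coef_tensor.upls_model <- function(object, ...) {
  B <- pls_scores_basis(object) %*% object$B_latent
  dims <- c(object$x_shape, object$y_shape)
  if (length(dims) == 1L) as.vector(B) else array(as.vector(B), dims)
}

#' Multi-pass blockwise iterative NPLS
#'
#' Offline NPLS variant that estimates every factor by alternating passes
#' over all data blocks: the covariance tensor is accumulated across blocks
#' before each rank-one step, and after a factor converges every block is
#' deflated.  With a single block this reduces to [fit_npls()].
#'
#' @param blocks non-empty list of \code{list(X = , Y = )} tensor pairs.
#' @param nfactors number of factors.
#' @param tol convergence tolerance on the concatenated score change.
#' @param max_iter maximum alternating passes per factor.
#' @return \code{"npls_model"} (scores are the concatenated per-block
#'   scores, in block order).
#' @export
fit_inpls <- function(blocks, nfactors, tol = 1e-8, max_iter = 100L) {
  if (!is.list(blocks) || length(blocks) == 0L)
    stop("'blocks' must be a non-empty list", call. = FALSE)
  dx1 <- tensor_dim(blocks[[1L]]$X)
  x_shape <- dx1[-1L]
  y_shape <- y_shape_of(blocks[[1L]]$Y)
  Ex <- lapply(blocks, function(b) unfold(b$X, 1L))
  Yu <- lapply(blocks, function(b) y_unfold(b$Y))
  Ey <- Yu
  ns <- vapply(Ex, nrow, 1L)
  n <- sum(ns)
  Yall <- do.call(rbind, Yu)
  Tm <- matrix(0, n, 0L)
  factors <- list()
  for (f in seq_len(nfactors)) {
    u <- lapply(Ey, function(E) {
      v <- E[, 1L]; if (sum(v^2) == 0) rep(1, nrow(E)) else v
    })
    t_old <- rep(0, n)
    ws <- NULL; qs <- NULL; tb <- NULL
    for (it in seq_len(max_iter)) {
      z <- 0
      for (b in seq_along(Ex))
        z <- z + sample_contract(fold(Ex[[b]], 1L, c(ns[b], x_shape)),
                                 u[[b]])
      if (sqrt(sum(z^2)) == 0) break
      ws <- rank_one_approx(if (length(x_shape) == 1L) as.vector(z) else z)$ws
      wk <- kron_rev(ws)
      tb <- lapply(Ex, function(E) as.vector(E %*% wk))
      if (length(y_shape) == 0L) {
        qs <- list()
        u <- lapply(Ey, function(E) E[, 1L])
      } else {
        v <- 0
        for (b in seq_along(Ey))
          v <- v + sample_contract(fold(Ey[[b]], 1L, c(ns[b], y_shape)),
                                   tb[[b]])
        r1y <- rank_one_approx(if (length(y_shape) == 1L) as.vector(v) else v)
        qs <- r1y$ws
        qk <- kron_rev(qs)
        u <- lapply(Ey, function(E) as.vector(E %*% qk))
      }
      tcat <- unlist(tb)
      if (sqrt(sum((tcat - t_old)^2)) <=
          tol * max(sqrt(sum(tcat^2)), 1e-300)) break
      t_old <- tcat
    }
    tcat <- unlist(tb)
    if (is.null(tb) || sqrt(sum(tcat^2)) < 1e-12) {
      warning("zero score norm at factor ", f, "; stopping early")
      break
    }
    Tm <- cbind(Tm, tcat)
    factors[[f]] <- list(w = ws, q = qs, t = tcat, u = unlist(u))
    wk <- kron_rev(ws)
    for (b in seq_along(Ex))
      Ex[[b]] <- Ex[[b]] - tcrossprod(tb[[b]], wk)
    Cf <- ls_solve(Tm, Yall)
    Yfit <- Tm %*% Cf
    off <- 0L
    for (b in seq_along(Ey)) {
      Ey[[b]] <- Yu[[b]] - Yfit[off + seq_len(ns[b]), , drop = FALSE]
      off <- off + ns[b]
    }
  }
  if (length(factors) == 0L)
    stop("no factors could be extracted", call. = FALSE)
  dimnames(Tm) <- NULL
  C_latent <- ls_solve(Tm, Yall)
  structure(list(
    factors = factors, T = Tm,
    C_latent = matrix(C_latent, nrow = ncol(Tm)),
    x_shape = x_shape, y_shape = y_shape, nfactors = length(factors),
    residual_norms = c(X = sqrt(sum(unlist(Ex)^2)),
                       Y = sqrt(sum((Yall - Tm %*% C_latent)^2)))
  ), class = "npls_model")
}
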