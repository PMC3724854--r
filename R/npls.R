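# N-way PLS for tensor input / tensor output.  Observation tensors carry the
# sample index in mode 1; Y may be a plain vector (scalar output per sample).
# No centering is applied by default: the model is a purely linear map of the
# vectorized input.

y_unfold <- function(Y) {
  if (is.null(dim(Y))) matrix(as.vector(Y), ncol = 1L) else unfold(Y, 1L)
}

y_shape_of <- function(Y) {
  d <- tensor_dim(Y)
  if (length(d) == 1L) integer(0) else d[-1L]
}

fold_output <- function(M, y_shape, n) {
  if (length(y_shape) == 0L) as.vector(M) else fold(M, 1L, c(n, y_shape))
}

# Least-squares solve via QR with a rank check kept lenient: scores produced
# by the extraction loop are well conditioned in non-degenerate problems.
ls_solve <- function(A, B) {
  qr.coef(qr(A), B)
}

#' Fit an N-way PLS regression model
#'
#' Extracts \code{nfactors} latent factors from the observation tensors
#' \code{X} (inputs, samples in mode 1) and \code{Y} (outputs, samples in
#' mode 1; a vector for scalar outputs).  Each factor consists of one
#' unit-norm projector per non-sample mode of \code{X} and of \code{Y},
#' obtained by rank-one decomposition of the covariance tensor between the
#' current residuals, so that the extracted scores maximize the covariance
#' between projected inputs and outputs.  After extraction the latent
#' regression coefficients are the least-squares fit of the unfolded output
#' on the score matrix.
#'
#' @param X input observation tensor, first mode of length \code{n}.
#' @param Y output observation tensor or vector, first mode of length
#'   \code{n}.
#' @param nfactors number of factors to extract (\code{>= 1}).
#' @param tol inner-loop relative tolerance on the change of the score
#'   vector.
#' @param max_iter maximum inner-loop iterations per factor.
#' @param quiet suppress early-termination warnings.
#' @return An object of class \code{"npls_model"}: list with
#'   \code{factors} (per factor: \code{w} projectors for X modes, \code{q}
#'   projectors for Y modes, score \code{t}, output score \code{u}),
#'   score matrix \code{T}, latent coefficients \code{C_latent}, shapes
#'   \code{x_shape}/\code{y_shape}, residual Frobenius norms and the number
#'   of factors actually extracted.
#' @export
fit_npls <- function(X, Y, nfactors, tol = 1e-8, max_iter = 100L,
                     quiet = FALSE) {
  check_tensor(X); check_tensor(Y)
  dx <- tensor_dim(X); n <- dx[1L]
  Yu <- y_unfold(Y)
  if (nrow(Yu) != n)
    stop("X and Y must share the first-mode (sample) length", call. = FALSE)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (nfactors < 1L) stop("'nfactors' must be >= 1", call. = FALSE)
  x_shape <- dx[-1L]
  y_shape <- y_shape_of(Y)
  if (length(x_shape) == 0L)
    stop("X must have at least one non-sample mode", call. = FALSE)

  Ex <- unfold(X, 1L)          # n x prod(x_shape), residual (unfolded)
  Ey <- Yu                     # n x max(prod(y_shape), 1)
  Tm <- matrix(0, n, 0L)
  factors <- list()
  for (f in seq_len(nfactors)) {
    if (sqrt(sum(Ex^2)) < 1e-12 * max(1, sqrt(sum(unfold(X, 1L)^2)))) {
      if (!quiet)
        warning("X residual is numerically zero after ", f - 1L,
                " factors; stopping early")
      break
    }
    u <- Ey[, 1L]
    if (sum(u^2) == 0) u <- rep(1, n)
    t_old <- rep(0, n)
    ws <- NULL; qs <- NULL; tf <- NULL
    for (it in seq_len(max_iter)) {
      z <- sample_contract(fold(Ex, 1L, dx), u)
      r1 <- rank_one_approx(z)
      ws <- r1$ws
      tf <- as.vector(Ex %*% kron_rev(ws))
      if (length(y_shape) == 0L) {
        qs <- list()
        u <- as.vector(Ey)
      } else {
        v <- sample_contract(fold(Ey, 1L, c(n, y_shape)), tf)
        if (sqrt(sum(v^2)) == 0) { qs <- list(); u <- tf; }
        else {
          r1y <- rank_one_approx(if (length(y_shape) == 1L) as.vector(v) else v)
          qs <- r1y$ws
          u <- as.vector(Ey %*% kron_rev(qs))
        }
      }
      if (sqrt(sum((tf - t_old)^2)) <= tol * max(sqrt(sum(tf^2)), 1e-300)) break
      t_old <- tf
      if (it == max_iter && !quiet)
        warning("inner loop did not converge for factor ", f,
                "; using last iterate")
    }
    if (sqrt(sum(tf^2)) < 1e-12) {
      if (!quiet)
        warning("zero score norm at factor ", f, "; stopping early")
      break
    }
    Tm <- cbind(Tm, tf)
    factors[[f]] <- list(w = ws, q = qs, t = tf, u = u)
    # deflate X by the factor's rank-one contribution
    wk <- kron_rev(ws)
    Ex <- Ex - tcrossprod(tf, wk)
    # Y-side deflation: running least-squares fit on all scores so far
    Cf <- ls_solve(Tm, Yu)
    Ey <- Yu - Tm %*% Cf
  }
  if (length(factors) == 0L)
    stop("no factors could be extracted (degenerate input)", call. = FALSE)
  dimnames(Tm) <- NULL
  C_latent <- ls_solve(Tm, Yu)
  structure(list(
    factors = factors,
    T = Tm,
    C_latent = matrix(C_latent, nrow = ncol(Tm)),
    x_shape = x_shape,
    y_shape = y_shape,
    nfactors = length(factors),
    residual_norms = c(X = sqrt(sum(Ex^2)),
                       Y = sqrt(sum((Yu - Tm %*% C_latent)^2)))
  ), class = "npls_model")
}

#' Project new observations onto the factors of an NPLS model
#'
#' Sequential scoring with deflation: for each factor the residual input is
#' projected onto the factor's mode projectors, then deflated by the
#' resulting rank-one contribution.  The map is linear in the input.
#'
#' @param model fitted \code{"npls_model"} (or the model inside an RNPLS
#'   state).
#' @param Xnew observation tensor whose non-sample modes match the training
#'   shape.
#' @return Score matrix of dimension \code{n_new} by \code{nfactors}.
#' @export
project_scores <- function(model, Xnew) {
  stopifnot(inherits(model, "npls_model"))
  d <- tensor_dim(Xnew)
  if (length(d) - 1L != length(model$x_shape) ||
      !all(d[-1L] == model$x_shape))
    stop("Xnew non-sample shape does not match the model", call. = FALSE)
  E <- unfold(Xnew, 1L)
  Tm <- matrix(0, d[1L], model$nfactors)
  for (f in seq_len(model$nfactors)) {
    wk <- kron_rev(model$factors[[f]]$w)
    tf <- as.vector(E %*% wk)
    Tm[, f] <- tf
    E <- E - tcrossprod(tf, wk)
  }
  Tm
}

#' Predict from an NPLS model
#'
#' @param object fitted \code{"npls_model"}.
#' @param Xnew observation tensor of new inputs.
#' @param ... unused.
#' @return Predicted output tensor with first-mode length
#'   \code{tensor_dim(Xnew)[1]} (a vector for scalar outputs).
#' @export
predict.npls_model <- function(object, Xnew, ...) {
  Tm <- project_scores(object, Xnew)
  fold_output(Tm %*% object$C_latent, object$y_shape, nrow(Tm))
}

#' Coefficient tensor of a fitted model
#'
#' Returns the unique linear map \code{B} such that prediction equals the
#' contraction of the vectorized input with \code{B}; computed by pushing
#' the canonical basis of the input space through the predictor.
#'
#' @param object a fitted model (\code{npls_model}, \code{pls_model},
#'   \code{upls_model} or \code{rnpls_state}).
#' @param ... unused.
#' @return Tensor of dimensions \code{c(x_shape, y_shape)}; for scalar
#'   outputs the dimensions are just \code{x_shape}.
#' @export
coef_tensor <- function(object, ...) UseMethod("coef_tensor")

#' @rdname coef_tensor
#' @export
coef_tensor.npls_model <- function(object, ...) {
  p <- prod(object$x_shape)
  E <- diag(p)
  Wm <- matrix(0, p, object$nfactors)
  for (f in seq_len(object$nfactors)) {
    wk <- kron_rev(object$factors[[f]]$w)
    tf <- as.vector(E %*% wk)
    Wm[, f] <- tf
    E <- E - tcrossprod(tf, wk)
  }
  B <- Wm %*% object$C_latent    # p x prod(y_shape)
  dims <- c(object$x_shape, object$y_shape)
  if (length(dims) == 1L) as.vector(B) else array(as.vector(B), dims)
}

#' @export
print.npls_model <- function(x, ...) {
  cat("N-way PLS model\n")
  cat("  factors:  ", x$nfactors, "\n")
  cat("  X shape:  ", paste(x$x_shape, collapse = " x "), "\n")
  cat("  Y shape:  ",
      if (length(x$y_shape) == 0L) "scalar"
      else paste(x$y_shape, collapse = " x "), "\n")
  cat("  residual norms:  X", format(x$residual_norms[["X"]], digits = 4),
      " Y", format(x$residual_norms[["Y"]], digits = 4), "\n")
  invisible(x)
}

# Contract new observations with a coefficient tensor: prediction route used
# in tests to confirm coef_tensor() reproduces predict().
#' Apply a coefficient tensor to new observations
#'
#' @param B coefficient tensor with dimensions \code{c(x_shape, y_shape)}.
#' @param Xnew observation tensor, samples in mode 1.
#' @param y_shape non-sample output dimensions (\code{integer(0)} for scalar
#'   outputs).
#' @return Predicted output tensor.
#' @export
apply_coef <- function(B, Xnew, y_shape = integer(0)) {
  n <- tensor_dim(Xnew)[1L]
  p <- prod(tensor_dim(Xnew)[-1L])
  Bm <- matrix(as.vector(B), nrow = p)
  fold_output(unfold(Xnew, 1L) %*% Bm, y_shape, n)
}
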