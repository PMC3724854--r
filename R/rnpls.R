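# Blockwise recursive N-way PLS.  Each incoming block is combined with a
# compressed summary of the past (loading tensors for the input and output
# sides, first mode of length nfactors), refit with batch NPLS, and the
# summary is rebuilt.  Past information can be down-weighted by a forgetting
# factor lambda in (0, 1].

#' Orthonormalize a score matrix
#'
#' Deterministic triangular factorization \code{T = T_orth \%*\% G} with
#' orthonormal \code{T_orth} and upper-triangular \code{G} with positive
#' diagonal.  Scores produced by NPLS are not orthogonal in general; the
#' recursive scheme requires orthonormal scores so that past data can be
#' captured exactly by loadings of fixed size.
#'
#' @param T score matrix (n by F) of full column rank.
#' @return List with \code{T_orth} (n by F, orthonormal columns) and
#'   \code{G} (F by F upper triangular, positive diagonal).
#' @export
orthonormalize_scores <- function(T) {
  T <- as.matrix(T)
  qrT <- qr(T)
  R <- qr.R(qrT)
  dR <- abs(diag(R))
  if (any(dR < 1e-10 * max(dR, 1e-300)))
    stop(paste("score matrix is rank deficient; reduce the number of",
               "factors (or enlarge the data block)"), call. = FALSE)
  Q <- qr.Q(qrT)
  s <- sign(diag(R))
  s[s == 0] <- 1
  list(T_orth = Q %*% diag(s, ncol(T)), G = diag(s, ncol(T)) %*% R)
}

#' Absorb a residual matrix into loadings
#'
#' Given the decomposition \code{X = T \%*\% t(P) + E} with
#' \code{T = T_orth \%*\% G}, returns updated loadings and residual such
#' that \code{X = T_orth \%*\% t(P_bar) + E_bar} with \code{E_bar}
#' orthogonal to the scores: \code{t(P_bar) = G \%*\% t(P) +
#' t(T_orth) \%*\% E} and \code{E_bar = E - T_orth \%*\% (t(T_orth) \%*\%
#' E)}.
#'
#' @param T_orth orthonormal score matrix (n by F).
#' @param G triangular factor with \code{T = T_orth \%*\% G}.
#' @param P loading matrix (p by F).
#' @param E residual matrix (n by p).
#' @return List with \code{P_bar} (p by F) and \code{E_bar} (n by p).
#' @export
absorb_residual <- function(T_orth, G, P, E) {
  T_orth <- as.matrix(T_orth); G <- as.matrix(G)
  P <- as.matrix(P); E <- as.matrix(E)
  if (nrow(T_orth) != nrow(E) || ncol(T_orth) != ncol(P) ||
      nrow(P) != ncol(E) || any(dim(G) != ncol(P)))
    stop("absorb_residual: inconsistent shapes", call. = FALSE)
  TtE <- crossprod(T_orth, E)            # F x p
  P_bar <- t(G %*% t(P) + TtE)           # p x F
  E_bar <- E - T_orth %*% TtE
  list(P_bar = P_bar, E_bar = E_bar)
}

# Compress a fitted NPLS model plus its data block into loading matrices.
# Returns P_bar (p x F), LY (F x q), plus diagnostics.
compress_block <- function(model, Xu, Yu) {
  Tm <- model$T
  on <- orthonormalize_scores(Tm)
  # X-side: X = T P' + E with P columns = Kronecker projectors per factor
  P <- vapply(model$factors, function(f) kron_rev(f$w),
              numeric(prod(model$x_shape)))
  P <- matrix(P, ncol = model$nfactors)
  E <- Xu - tcrossprod(Tm, P)
  ab <- absorb_residual(on$T_orth, on$G, P, E)
  # Y-side: loadings chosen as T_orth' Y so the output residual is orthogonal
  # to the scores by construction (equivalently G C_latent' absorbed with the
  # output residual projection).
  LY <- crossprod(on$T_orth, Yu)         # F x q
  rss <- sqrt(sum(ab$E_bar^2))
  sig <- sqrt(sum(Xu^2))
  Ey <- Yu - on$T_orth %*% LY
  list(PX = ab$P_bar, LY = LY,
       resid_ratio = if (sig > 0) rss / sig else 0,
       # orthogonality certificates of the compression step
       orth_error = max(abs(crossprod(on$T_orth) -
                              diag(ncol(on$T_orth)))),
       x_resid_orth = max(abs(crossprod(on$T_orth, ab$E_bar))),
       y_resid_orth = max(abs(crossprod(on$T_orth, Ey))))
}

new_rnpls_state <- function(model, PX, LY, nfactors, lambda, n_seen,
                            diagnostics) {
  structure(list(
    nfactors = nfactors,
    lambda = lambda,
    L_X = fold(t(PX), 1L, c(nfactors, model$x_shape)),
    L_Y = if (length(model$y_shape) == 0L) as.vector(LY)
          else fold(LY, 1L, c(nfactors, model$y_shape)),
    model = model,
    n_seen = n_seen,
    diagnostics = diagnostics
  ), class = "rnpls_state")
}

#' Initialize a recursive NPLS state from the first data block
#'
#' Fits batch NPLS on the first block, orthonormalizes the scores, absorbs
#' the input residual into the input-side loadings and stores the projected
#' outputs as output-side loadings.  The resulting state summarizes the
#' block by loading tensors whose first mode has length \code{nfactors},
#' independent of the block size.
#'
#' @param X1,Y1 first block of observations (samples in mode 1).
#' @param nfactors number of latent factors maintained by the state.
#' @param lambda forgetting factor in \code{(0, 1]}; 1 means no forgetting.
#' @param ... passed to [fit_npls()].
#' @return Object of class \code{"rnpls_state"}.
#' @export
rnpls_init <- function(X1, Y1, nfactors, lambda = 1, ...) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 ||
      lambda > 1)
    stop("'lambda' must be in (0, 1]", call. = FALSE)
  n1 <- tensor_dim(X1)[1L]
  if (n1 < nfactors)
    stop("first block must contain at least 'nfactors' samples",
         call. = FALSE)
  model <- fit_npls(X1, Y1, nfactors, ...)
  if (model$nfactors < nfactors)
    stop("requested number of factors exceeds the achievable rank of the ",
         "first block; reduce 'nfactors'", call. = FALSE)
  cb <- compress_block(model, unfold(X1, 1L), y_unfold(Y1))
  new_rnpls_state(model, cb$PX, cb$LY, nfactors, lambda, n1,
                  cb[c("resid_ratio", "orth_error", "x_resid_orth",
                       "y_resid_orth")])
}

#' Update a recursive NPLS state with a new block
#'
#' Stacks the forgetting-weighted loading tensors of the state on top of the
#' new block, refits batch NPLS with the same number of factors on the
#' stacked tensors, and rebuilds the compressed loadings.  With
#' \code{lambda = 1} and data of exact factor structure this reproduces the
#' batch fit on all data seen so far; with \code{lambda < 1} older blocks
#' are geometrically down-weighted.  The state is immutable: a new state is
#' returned.
#'
#' @param state an \code{"rnpls_state"}.
#' @param Xb,Yb new block of observations (samples in mode 1, shapes
#'   matching the state).
#' @param ... passed to [fit_npls()].
#' @return Updated \code{"rnpls_state"}.
#' @export
rnpls_update <- function(state, Xb, Yb, ...) {
  stopifnot(inherits(state, "rnpls_state"))
  db <- tensor_dim(Xb)
  nb <- db[1L]
  if (nb < 1L) stop("block must contain at least one sample", call. = FALSE)
  if (!all(db[-1L] == state$model$x_shape))
    stop("block X shape does not match the state", call. = FALSE)
  Ybu <- y_unfold(Yb)
  if (nrow(Ybu) != nb)
    stop("block X and Y sample counts differ", call. = FALSE)
  ysh <- y_shape_of(Yb)
  if (length(ysh) != length(state$model$y_shape) ||
      !all(ysh == state$model$y_shape))
    stop("block Y shape does not match the state", call. = FALSE)

  Fc <- state$nfactors
  lam <- state$lambda
  Xs <- rbind(lam * unfold(state$L_X, 1L), unfold(Xb, 1L))
  Ys <- rbind(lam * y_unfold(state$L_Y), Ybu)
  xsh <- state$model$x_shape
  Xst <- fold(Xs, 1L, c(Fc + nb, xsh))
  Yst <- if (length(ysh) == 0L) as.vector(Ys)
         else fold(Ys, 1L, c(Fc + nb, ysh))
  model <- fit_npls(Xst, Yst, Fc, ...)
  if (model$nfactors < Fc)
    stop("factor extraction collapsed during the update; reduce ",
         "'nfactors' or enlarge the block", call. = FALSE)
  cb <- compress_block(model, Xs, Ys)
  new_rnpls_state(model, cb$PX, cb$LY, Fc, lam, state$n_seen + nb,
                  cb[c("resid_ratio", "orth_error", "x_resid_orth",
                       "y_resid_orth")])
}

#' Predict from a recursive NPLS state
#'
#' @param object an \code{"rnpls_state"}.
#' @param Xnew observation tensor of new inputs.
#' @param ... unused.
#' @return Predicted output tensor (vector for scalar outputs).
#' @export
predict.rnpls_state <- function(object, Xnew, ...) {
  predict(object$model, Xnew)
}

#' @rdname coef_tensor
#' @export
coef_tensor.rnpls_state <- function(object, ...) {
  coef_tensor(object$model)
}

#' @export
print.rnpls_state <- function(x, ...) {
  cat("Recursive N-way PLS state\n")
  cat("  factors:         ", x$nfactors, "\n")
  cat("  forgetting:      ", x$lambda, "\n")
  cat("  samples seen:    ", x$n_seen, "\n")
  cat("  last block residual/signal: ",
      format(x$diagnostics$resid_ratio, digits = 4), "\n")
  invisible(x)
}
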