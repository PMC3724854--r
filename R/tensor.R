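# Dense tensors are plain R arrays; a numeric vector is an order-1 tensor and a
# matrix an order-2 tensor.  Mode 1 always indexes observations in the modelling
# code.  Unfolding follows the convention with remaining modes in ascending
# order and earlier modes varying fastest, which matches R's column-major
# storage after rotating the unfolded mode to the front.

#' Dimensions of a tensor
#'
#' @param x numeric vector, matrix or array.
#' @return Integer vector of mode sizes; a plain vector has one mode.
#' @export
tensor_dim <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else as.integer(d)
}

#' Order (number of modes) of a tensor
#'
#' @param x numeric vector, matrix or array.
#' @return Integer scalar.
#' @export
tensor_order <- function(x) length(tensor_dim(x))

check_tensor <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x))
    stop(sprintf("'%s' must be numeric", arg), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  invisible(x)
}

#' Unfold (matricize) a tensor along one mode
#'
#' Rearranges tensor \code{x} into a matrix whose rows index the chosen mode.
#' Columns run over the remaining modes in ascending order, with earlier modes
#' varying fastest.
#'
#' @param x numeric array (or vector/matrix).
#' @param mode mode index, between 1 and \code{tensor_order(x)}.
#' @return Matrix of dimension \code{I_mode} by \code{prod(I_other)}.
#' @seealso [fold()] for the inverse operation.
#' @export
unfold <- function(x, mode) {
  d <- tensor_dim(x)
  n <- length(d)
  if (length(mode) != 1L || mode < 1L || mode > n)
    stop(sprintf("'mode' must be in 1..%d", n), call. = FALSE)
  if (n == 1L) return(matrix(as.vector(x), nrow = d, ncol = 1L))
  if (mode != 1L) x <- aperm(array(x, d), c(mode, seq_len(n)[-mode]))
  matrix(as.vector(x), nrow = d[mode], ncol = prod(d[-mode]))
}

#' Fold a matrix back into a tensor
#'
#' Inverse of [unfold()]: restores the tensor of dimensions \code{dims} from
#' its mode-\code{mode} unfolding.
#'
#' @param m matrix as produced by \code{unfold}.
#' @param mode mode along which \code{m} was unfolded.
#' @param dims target tensor dimensions.
#' @return Array with \code{dim = dims} (a vector if \code{length(dims) == 1}).
#' @export
fold <- function(m, mode, dims) {
  dims <- as.integer(dims)
  n <- length(dims)
  if (length(mode) != 1L || mode < 1L || mode > n)
    stop(sprintf("'mode' must be in 1..%d", n), call. = FALSE)
  if (length(m) != prod(dims))
    stop("length of 'm' does not match prod(dims)", call. = FALSE)
  if (n == 1L) return(as.vector(m))
  a <- array(as.vector(m), dims[c(mode, seq_len(n)[-mode])])
  if (mode == 1L) return(a)
  aperm(a, order(c(mode, seq_len(n)[-mode])))
}

#' Vectorize a tensor
#'
#' Flattens a tensor to a vector with mode 1 varying fastest, so that
#' \code{vectorize(outer_prod(list(w1, ..., wM)))} equals the Kronecker
#' product \code{wM \%x\% ... \%x\% w1}.
#'
#' @param x numeric vector, matrix or array.
#' @return Numeric vector of length \code{prod(tensor_dim(x))}.
#' @export
vectorize <- function(x) as.vector(x)

#' Outer product of a list of vectors
#'
#' @param vs non-empty list of non-empty numeric vectors.
#' @return Tensor of order \code{length(vs)} with element
#'   \code{(i1, ..., iM)} equal to \code{prod(vs[[k]][ik])}.
#' @export
outer_prod <- function(vs) {
  if (!is.list(vs) || length(vs) == 0L)
    stop("'vs' must be a non-empty list of vectors", call. = FALSE)
  if (any(vapply(vs, length, 1L) == 0L))
    stop("'vs' contains an empty vector", call. = FALSE)
  out <- as.vector(vs[[1L]])
  for (k in seq_along(vs)[-1L]) out <- outer(out, as.vector(vs[[k]]))
  if (length(vs) == 1L) out else array(out, vapply(vs, length, 1L))
}

# Kronecker product of the reversed list, i.e. vectorize(outer_prod(vs)).
# Used wherever a set of mode projectors is applied to an unfolded tensor.
kron_rev <- function(vs) {
  if (length(vs) == 0L) return(1)
  out <- as.vector(vs[[1L]])
  for (k in seq_along(vs)[-1L]) out <- kronecker(as.vector(vs[[k]]), out)
  out
}

#' Contract a tensor along its sample (first) mode
#'
#' Computes the weighted sum of first-mode slices,
#' \code{sum_n u[n] * x[n, ...]}.  This is the covariance tensor formed inside
#' each NPLS factor extraction.
#'
#' @param x tensor whose first mode has length \code{length(u)}.
#' @param u numeric weight vector.
#' @return Tensor of dimensions \code{tensor_dim(x)[-1]}; a scalar when
#'   \code{x} is order-1.
#' @export
sample_contract <- function(x, u) {
  d <- tensor_dim(x)
  if (length(u) != d[1L])
    stop("length(u) must equal the first-mode length of 'x'", call. = FALSE)
  res <- as.vector(crossprod(unfold(x, 1L), as.vector(u)))
  if (length(d) == 1L) return(res)          # order-1 x: scalar
  if (length(d) == 2L) return(res)          # order-2 x: vector of length d[2]
  array(res, d[-1L])
}

#' Best rank-one approximation of a tensor
#'
#' Alternating least squares fit of \code{z} by
#' \code{scale * w1 o w2 o ... o wM} with unit-norm factor vectors.  For an
#' order-2 input the leading singular pair is returned directly.  The sign
#' convention makes the largest-magnitude entry of every factor vector
#' positive, with signs absorbed into \code{scale}.
#'
#' @param z non-zero numeric tensor.
#' @param tol relative tolerance on the change of \code{scale} between
#'   alternating sweeps.
#' @param max_iter maximum number of sweeps; on non-convergence the last
#'   iterate is returned with a warning and \code{converged = FALSE}.
#' @return List with unit vectors \code{ws} (one per mode), \code{scale}, and
#'   \code{converged}.
#' @export
rank_one_approx <- function(z, tol = 1e-10, max_iter = 200L) {
  check_tensor(z)
  d <- tensor_dim(z)
  if (sqrt(sum(z^2)) == 0)
    stop("rank_one_approx: input tensor is zero", call. = FALSE)
  M <- length(d)
  fix_signs <- function(ws, scale) {
    for (k in seq_along(ws)) {
      s <- sign(ws[[k]][which.max(abs(ws[[k]]))])
      ws[[k]] <- ws[[k]] * s
      scale <- scale * s
    }
    list(ws = ws, scale = scale, converged = TRUE)
  }
  if (M == 1L) {
    nrm <- sqrt(sum(z^2))
    return(fix_signs(list(as.vector(z) / nrm), nrm))
  }
  if (M == 2L) {
    sv <- svd(array(z, d), nu = 1L, nv = 1L)
    return(fix_signs(list(as.vector(sv$u), as.vector(sv$v)), sv$d[1L]))
  }
  # ALS for order >= 3; initialize each factor from the largest-norm column of
  # the corresponding mode unfolding (deterministic, handles degenerate ties).
  ws <- vector("list", M)
  for (k in 2:M) {
    Zk <- unfold(z, k)
    col <- Zk[, which.max(colSums(Zk^2))]
    ws[[k]] <- col / sqrt(sum(col^2))
  }
  scale <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (k in seq_len(M)) {
      v <- kron_rev(ws[-k])
      wk <- as.vector(unfold(z, k) %*% v)
      nk <- sqrt(sum(wk^2))
      if (nk == 0) stop("rank_one_approx: degenerate zero contraction",
                        call. = FALSE)
      ws[[k]] <- wk / nk
    }
    new_scale <- nk
    if (it > 1L && abs(new_scale - scale) <= tol * abs(new_scale)) {
      scale <- new_scale
      converged <- TRUE
      break
    }
    scale <- new_scale
  }
  if (!converged)
    warning("rank_one_approx did not converge in ", max_iter, " sweeps")
  out <- fix_signs(ws, scale)
  out$converged <- converged
  out
}
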