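# Programmatic fixtures shared across test files.

# Random dense tensor with reproducible entries.
rand_tensor <- function(dims, seed = 1) {
  set.seed(seed)
  if (length(dims) == 1L) rnorm(dims) else array(rnorm(prod(dims)), dims)
}

# Data with exact F-factor structure whose mode projectors are orthonormal
# within each mode ("doubly orthonormal").  For such data the rank-one
# extraction recovers the factors exactly, the training residual is zero
# after F factors, and recursive/batch equivalence holds to machine
# precision.
make_exact_factor_data <- function(n, J1, J2, nfactors, seed = 1,
                                   y_shape = NULL) {
  set.seed(seed)
  W1 <- qr.Q(qr(matrix(rnorm(J1 * nfactors), J1)))
  W2 <- qr.Q(qr(matrix(rnorm(J2 * nfactors), J2)))
  Tt <- matrix(rnorm(n * nfactors), n)
  Xu <- matrix(0, n, J1 * J2)
  for (f in seq_len(nfactors))
    Xu <- Xu + tcrossprod(Tt[, f], kronecker(W2[, f], W1[, f]))
  X <- fold(Xu, 1, c(n, J1, J2))
  if (is.null(y_shape)) {
    Y <- as.vector(Tt %*% rnorm(nfactors))
  } else {
    C <- matrix(rnorm(nfactors * prod(y_shape)), nfactors)
    Y <- fold(Tt %*% C, 1, c(n, y_shape))
  }
  list(X = X, Y = Y, T = Tt, W1 = W1, W2 = W2)
}

# Split sample-mode tensors/vectors into consecutive equal blocks.
block_split <- function(X, Y, n_blocks) {
  n <- tensor_dim(X)[1]
  bs <- n %/% n_blocks
  lapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1) * bs + 1):(b * bs)
    list(X = if (tensor_order(X) == 1) X[idx]
             else fold(unfold(X, 1)[idx, , drop = FALSE], 1,
                       c(length(idx), tensor_dim(X)[-1])),
         Y = if (tensor_order(Y) == 1) Y[idx]
             else fold(unfold(Y, 1)[idx, , drop = FALSE], 1,
                       c(length(idx), tensor_dim(Y)[-1])))
  })
}

# Run blockwise RNPLS over a list of blocks and return the final state.
run_rnpls_blocks <- function(blocks, nfactors, lambda = 1, ...) {
  st <- rnpls_init(blocks[[1]]$X, blocks[[1]]$Y, nfactors, lambda, ...)
  for (b in blocks[-1]) st <- rnpls_update(st, b$X, b$Y, ...)
  st
}

rel_fro <- function(A, B) {
  sqrt(sum((as.vector(A) - as.vector(B))^2)) / sqrt(sum(as.vector(B)^2))
}
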