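# Independent oracles, deliberately written from the textbook definitions
# and kept free of any code path under R/.

# Textbook PLS1 (NIPALS, scalar response, X- and y-deflation, no
# normalization tricks).  Returns fitted values and the coefficient vector
# B = W (P'W)^{-1} q.
pls1_reference <- function(X, y, nfactors) {
  X <- as.matrix(X)
  E <- X; f <- as.vector(y)
  W <- NULL; P <- NULL; Q <- NULL
  for (k in seq_len(nfactors)) {
    w <- as.vector(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    p <- as.vector(crossprod(E, t)) / tt
    q <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - q * t
    W <- cbind(W, w); P <- cbind(P, p); Q <- c(Q, q)
  }
  B <- W %*% solve(crossprod(P, W), Q)
  list(B = as.vector(B), fitted = as.vector(X %*% B))
}

# Brute-force elementwise mode-m unfolding straight from the index formula:
# element (i1,...,iN) lands at row i_mode and column
# 1 + sum_{k != mode} (i_k - 1) * prod_{m < k, m != mode} I_m.
unfold_bruteforce <- function(x, mode) {
  d <- tensor_dim(x)
  xa <- array(x, d)
  out <- matrix(0, d[mode], prod(d[-mode]))
  idx_grid <- as.matrix(expand.grid(lapply(d, seq_len)))
  rest <- setdiff(seq_along(d), mode)
  for (r in seq_len(nrow(idx_grid))) {
    ii <- idx_grid[r, ]
    col <- 1
    mult <- 1
    for (k in rest) {
      col <- col + (ii[k] - 1) * mult
      mult <- mult * d[k]
    }
    out[ii[mode], col] <- xa[matrix(ii, 1)]
  }
  out
}

# Direct time-domain Morlet wavelet coefficients: naive O(n m) evaluation of
# the standard correlation with the conjugate wavelet,
# W(i) = sum_u x[i + u] conj(psi(u)).
morlet_direct <- function(x, srate, freq, width) {
  sigma_t <- width / (2 * pi * freq)
  half <- ceiling(4 * sigma_t * srate)
  tt <- seq(-half, half) / srate
  psi <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sigma_t^2))
  psi <- psi / sqrt(sum(Mod(psi)^2))
  n <- length(x)
  out <- complex(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i] <- sum(x[lo:hi] * Conj(psi[(lo:hi) - i + half + 1]))
  }
  out
}
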