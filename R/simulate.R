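# Synthetic two-class tensor data: each sample is a J_time x J_freq matrix
# equal to one of two smooth class templates plus Gaussian noise with a
# Kronecker (time x frequency) covariance.  Binary labels are balanced
# Bernoulli draws; an optional change point reverses the class-template
# assignment mid-stream to emulate an abrupt non-stationarity.

# Evaluate thunk with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic two-class generator.  Defaults
#' mirror the benchmark conditions: 16 x 16 time-frequency samples, smooth
#' squared-exponential mode covariances with lengthscales 3.0 (time) and 2.0
#' (frequency), and noise expressed as a percentage of the class-signal
#' amplitude (100 means the noise RMS equals the RMS of half the
#' between-class template difference).
#'
#' @param n number of samples (>= 2).
#' @param noise_percent noise standard deviation as percent of signal
#'   amplitude (>= 0).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   configuration.
#' @param J_time,J_freq mode sizes of each sample matrix.
#' @param change_point optional index in \code{1..n-1}; labels generated
#'   after this sample have their class-template assignment reversed.
#' @param covariance_lengthscales length-2 positive numeric, squared-
#'   exponential lengthscales for the time and frequency modes.
#' @param template_spec list of template parameters: \code{n_bumps} Gaussian
#'   bumps per pattern, bump \code{width} range (in grid units), and
#'   \code{background_scale}, the Frobenius norm of the shared smooth
#'   background (the between-class difference always has unit Frobenius
#'   norm).
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(n, noise_percent = 100, seed = 1L,
                       J_time = 16L, J_freq = 16L,
                       change_point = NULL,
                       covariance_lengthscales = c(3.0, 2.0),
                       template_spec = list(n_bumps = 3L,
                                            width = c(0.6, 1.5),
                                            background_scale = 5)) {
  if (!is.numeric(n) || n < 2L) stop("'n' must be >= 2", call. = FALSE)
  if (noise_percent < 0) stop("'noise_percent' must be >= 0", call. = FALSE)
  if (!is.null(change_point)) {
    if (change_point < 1L || change_point >= n)
      stop("'change_point' must satisfy 1 <= change_point < n",
           call. = FALSE)
  }
  if (length(covariance_lengthscales) != 2L ||
      any(covariance_lengthscales <= 0))
    stop("'covariance_lengthscales' must be two positive numbers",
         call. = FALSE)
  structure(list(n = as.integer(n), noise_percent = noise_percent,
                 seed = as.integer(seed), J_time = as.integer(J_time),
                 J_freq = as.integer(J_freq),
                 change_point = if (is.null(change_point)) NULL
                                else as.integer(change_point),
                 covariance_lengthscales = covariance_lengthscales,
                 template_spec = template_spec),
            class = "sim_config")
}

#' Squared-exponential mode covariance
#'
#' Symmetric positive-definite \code{J x J} matrix with entry
#' \code{exp(-(i - j)^2 / (2 * lengthscale^2))} plus a ridge of
#' \code{1e-8} on the diagonal, emulating the smooth within-mode
#' correlations of band-limited electrophysiological features.
#'
#' @param J matrix size (>= 1).
#' @param lengthscale positive correlation lengthscale in grid units.
#' @return \code{J x J} covariance matrix.
#' @export
make_covariance <- function(J, lengthscale) {
  if (J < 1L) stop("'J' must be >= 1", call. = FALSE)
  if (lengthscale <= 0) stop("'lengthscale' must be > 0", call. = FALSE)
  idx <- seq_len(J)
  D <- outer(idx, idx, "-")
  exp(-D^2 / (2 * lengthscale^2)) + diag(1e-8, J)
}

# smooth 1-D profile: sum of Gaussian bumps at seeded random centers
gaussian_profile <- function(J, n_bumps, width) {
  g <- seq_len(J)
  p <- numeric(J)
  for (b in seq_len(n_bumps)) {
    ct <- stats::runif(1, 1, J)
    sd_b <- stats::runif(1, width[1L], width[2L])
    amp <- stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1L)
    p <- p + amp * exp(-(g - ct)^2 / (2 * sd_b^2))
  }
  p
}

#' Generate the two class templates
#'
#' Builds a shared smooth background plus/minus half a smooth difference
#' pattern.  Both patterns are separable products of per-mode profiles,
#' each profile a sum of seeded random Gaussian bumps; the difference
#' profiles are orthogonalized against the background profiles mode by
#' mode, so background and class difference occupy orthogonal directions
#' in every modality.  The between-class difference is normalized to unit
#' Frobenius norm and the background to
#' \code{template_spec$background_scale}.  Deterministic given the seed.
#'
#' @param J_time,J_freq template dimensions.
#' @param template_spec see [sim_config()].
#' @param seed integer seed.
#' @return List with matrices \code{X0} and \code{X1}
#'   (\code{norm(X1 - X0, "F") == 1}).
#' @export
make_templates <- function(J_time, J_freq,
                           template_spec = list(n_bumps = 3L,
                                                width = c(0.6, 1.5),
                                                background_scale = 5),
                           seed = 1L) {
  with_seed(seed + 104729L, {
    draw <- function(J) gaussian_profile(J, template_spec$n_bumps,
                                         template_spec$width)
    unitize <- function(v) {
      nv <- sqrt(sum(v^2))
      if (nv < 1e-10) stop("degenerate template profile", call. = FALSE)
      v / nv
    }
    bt <- unitize(draw(J_time)); bf <- unitize(draw(J_freq))
    # difference profiles, orthogonal to the background in each mode
    dt <- draw(J_time); dt <- unitize(dt - bt * sum(dt * bt))
    df <- draw(J_freq); df <- unitize(df - bf * sum(df * bf))
    bg <- template_spec$background_scale * outer(bt, bf)
    diff <- outer(dt, df)              # unit Frobenius norm by construction
    list(X0 = bg - diff / 2, X1 = bg + diff / 2)
  })
}

#' True regression coefficients of the generator
#'
#' The normalized difference of the class templates; the direction a
#' regression of the labels on the noiseless inputs recovers (up to scale
#' and an intercept-like background component).
#'
#' @param templates list with \code{X0}, \code{X1} as from
#'   [make_templates()].
#' @return Matrix of unit Frobenius norm.
#' @export
true_coefficients <- function(templates) {
  D <- templates$X1 - templates$X0
  nf <- sqrt(sum(D^2))
  if (nf < 1e-12)
    stop("templates are identical: zero class signal", call. = FALSE)
  D / nf
}

#' Sample a labeled synthetic dataset
#'
#' Draws balanced Bernoulli labels and sample matrices equal to the
#' corresponding class template plus Kronecker-covariance Gaussian noise.
#' The noise field is \code{sigma * eps} with
#' \code{vec(eps) ~ N(0, C_freq (x) C_time)} scaled to unit average
#' per-element variance, and
#' \code{sigma = noise_percent / 100 * A} where \code{A} is the
#' root-mean-square element amplitude of half the template difference.
#' After an optional change point the class-template assignment of the
#' labels is reversed.
#'
#' @param config a [sim_config()].
#' @return Object of class \code{"labeled_dataset"}: list with input tensor
#'   \code{X} (\code{n x J_time x J_freq}), labels \code{y} in
#'   \code{\{0, 1\}}, \code{templates}, \code{B_true} and the \code{config}.
#' @export
sample_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tpl <- make_templates(config$J_time, config$J_freq, config$template_spec,
                        config$seed)
  Ct <- make_covariance(config$J_time, config$covariance_lengthscales[1L])
  Cf <- make_covariance(config$J_freq, config$covariance_lengthscales[2L])
  Lt <- t(chol(Ct)); Lf <- t(chol(Cf))
  avar <- mean(diag(Ct)) * mean(diag(Cf))
  D <- tpl$X1 - tpl$X0
  A <- sqrt(mean((D / 2)^2))
  sigma <- config$noise_percent / 100 * A
  n <- config$n
  with_seed(config$seed, {
    y <- stats::rbinom(n, 1L, 0.5)
    cls <- y
    if (!is.null(config$change_point)) {
      flip <- seq_len(n) > config$change_point
      cls[flip] <- 1L - cls[flip]
    }
    X <- array(0, c(n, config$J_time, config$J_freq))
    for (i in seq_len(n)) {
      Z <- matrix(stats::rnorm(config$J_time * config$J_freq),
                  config$J_time, config$J_freq)
      eps <- (Lt %*% Z %*% t(Lf)) / sqrt(avar)
      X[i, , ] <- (if (cls[i] == 1L) tpl$X1 else tpl$X0) + sigma * eps
    }
    structure(list(X = X, y = y, templates = tpl,
                   B_true = true_coefficients(tpl), config = config),
              class = "labeled_dataset")
  })
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Synthetic labeled dataset\n")
  cat("  samples:      ", x$config$n, "\n")
  cat("  sample shape: ", x$config$J_time, "x", x$config$J_freq, "\n")
  cat("  noise:        ", x$config$noise_percent, "%\n")
  if (!is.null(x$config$change_point))
    cat("  change point: ", x$config$change_point, "\n")
  invisible(x)
}
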