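# Feature-tensor construction for multichannel electrophysiology: common
# average reference filtering and complex-Morlet continuous wavelet
# transform mapped to (epoch x window x frequency x channel) tensors.

#' Common average reference filter
#'
#' Subtracts the instantaneous across-channel mean from every channel,
#' removing any signal component common to all electrodes.
#'
#' @param raw numeric matrix, timepoints by channels.
#' @return Matrix of the same shape with zero row means.
#' @export
car_filter <- function(raw) {
  raw <- as.matrix(raw)
  check_tensor(raw)
  raw - rowMeans(raw)
}

#' Epoched multichannel signal specification
#'
#' Describes how a continuous recording is cut into epochs and how each
#' epoch is tiled with sliding analysis windows.
#'
#' @param raw numeric matrix, timepoints by channels.
#' @param srate sampling rate in Hz.
#' @param epoch_ends integer sample indices marking the final sample of
#'   each epoch.
#' @param epoch_length epoch duration in seconds (the epoch covers the
#'   interval ending at \code{epoch_ends}).
#' @param window_length sliding-window length in seconds.
#' @param window_step sliding-window step in seconds.
#' @param freqs numeric vector of analysis frequencies in Hz (below
#'   Nyquist).
#' @return Object of class \code{"epoched_signal"}.
#' @export
epoched_signal <- function(raw, srate, epoch_ends, epoch_length,
                           window_length, window_step, freqs) {
  raw <- as.matrix(raw)
  check_tensor(raw)
  if (srate <= 0) stop("'srate' must be positive", call. = FALSE)
  if (any(freqs <= 0) || any(freqs >= srate / 2))
    stop("'freqs' must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  ep_len <- round(epoch_length * srate)
  if (ep_len < 2L) stop("epoch too short", call. = FALSE)
  if (any(epoch_ends > nrow(raw)) || any(epoch_ends < ep_len))
    stop("epochs fall outside the signal", call. = FALSE)
  win_len <- round(window_length * srate)
  win_step <- max(1L, round(window_step * srate))
  if (win_len < 1L || win_len > ep_len)
    stop("window grid does not fit inside the epoch", call. = FALSE)
  structure(list(raw = raw, srate = srate,
                 epoch_ends = as.integer(epoch_ends),
                 epoch_length = epoch_length,
                 window_length = window_length, window_step = window_step,
                 freqs = as.numeric(freqs),
                 ep_len = as.integer(ep_len), win_len = as.integer(win_len),
                 win_step = as.integer(win_step)),
            class = "epoched_signal")
}

# Complex Morlet wavelet coefficients of one channel at one frequency,
# computed by FFT convolution over the whole recording.  width = number of
# cycles; the Gaussian envelope has sd sigma_t = width / (2 pi f).
morlet_cwt <- function(x, srate, freq, width) {
  n <- length(x)
  sigma_t <- width / (2 * pi * freq)
  half <- ceiling(4 * sigma_t * srate)
  tt <- seq(-half, half) / srate
  psi <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sigma_t^2))
  psi <- psi / sqrt(sum(Mod(psi)^2))       # unit-energy normalization
  m <- length(psi)
  nfft <- stats::nextn(n + m - 1L, 2L)
  conv <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                     stats::fft(c(psi, rep(0, nfft - m))),
                     inverse = TRUE) / nfft
  # center the kernel: coefficient i uses samples i-half .. i+half
  conv[half + seq_len(n)]
}

# margin (in samples) contaminated by convolution edges at frequency f
morlet_margin <- function(srate, freq, width) {
  ceiling(4 * width / (2 * pi * freq) * srate)
}

#' Continuous wavelet transform feature tensor
#'
#' Maps every epoch to a (window x frequency x channel) array of
#' time-frequency features: complex Morlet wavelet magnitudes are computed
#' per channel and frequency, and each sliding window is summarized by the
#' root-mean-square magnitude (alternatives: mean or max).  Epochs must be
#' located so that no analysis window overlaps the convolution edges of the
#' recording; otherwise an error is raised rather than silently
#' zero-padding.
#'
#' @param sig an [epoched_signal()].
#' @param wavelet_width Morlet width in cycles (default 7).
#' @param summary one of \code{"rms"}, \code{"mean"}, \code{"max"}:
#'   per-window summary of the coefficient magnitudes.
#' @return Tensor of dimensions (epochs, windows, frequencies, channels).
#' @export
cwt_feature_tensor <- function(sig, wavelet_width = 7,
                               summary = c("rms", "mean", "max")) {
  stopifnot(inherits(sig, "epoched_signal"))
  summary <- match.arg(summary)
  n <- nrow(sig$raw); n_ch <- ncol(sig$raw)
  n_win <- (sig$ep_len - sig$win_len) %/% sig$win_step + 1L
  n_freq <- length(sig$freqs)
  n_ep <- length(sig$epoch_ends)
  margin <- max(vapply(sig$freqs, morlet_margin, numeric(1),
                       srate = sig$srate, width = wavelet_width))
  starts <- sig$epoch_ends - sig$ep_len + 1L
  if (any(starts <= margin) || any(sig$epoch_ends > n - margin))
    stop("epochs too close to the recording edges for the wavelet ",
         "support; provide at least ", margin, " samples of padding",
         call. = FALSE)
  summarize <- switch(summary,
                      rms = function(v) sqrt(mean(v^2)),
                      mean = mean,
                      max = max)
  out <- array(0, c(n_ep, n_win, n_freq, n_ch))
  win_offsets <- (seq_len(n_win) - 1L) * sig$win_step
  for (ch in seq_len(n_ch)) {
    for (fi in seq_len(n_freq)) {
      mag <- Mod(morlet_cwt(sig$raw[, ch], sig$srate, sig$freqs[fi],
                            wavelet_width))
      for (e in seq_len(n_ep)) {
        s0 <- starts[e]
        for (w in seq_len(n_win)) {
          idx <- s0 + win_offsets[w] + seq_len(sig$win_len) - 1L
          out[e, w, fi, ch] <- summarize(mag[idx])
        }
      }
    }
  }
  out
}
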