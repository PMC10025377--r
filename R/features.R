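#' Morlet wavelet feature tensorization
#'
#' Multichannel neural time series are cut into sliding epochs, transformed
#' with a complex Morlet continuous wavelet transform at a set of analysis
#' frequencies, and the transform magnitudes are averaged within contiguous
#' temporal bins, yielding one temporal-frequency-spatial feature tensor per
#' epoch (10 x 15 x 64 under the defaults: 1-s epochs at 586 Hz, 100-ms
#' steps, 10-150 Hz in 10-Hz steps, 10 temporal bins).
#'
#' @name features
NULL

#' Epoching / tensorization configuration
#'
#' @param fs sampling rate in Hz (default 586).
#' @param window epoch length in seconds (default 1).
#' @param step sliding step in seconds (default 0.1).
#' @param freqs analysis frequencies in Hz, strictly increasing (default
#'   `seq(10, 150, by = 10)`); all must be below Nyquist.
#' @param n_time_bins number of contiguous temporal averaging bins
#'   (default 10).
#' @param omega0 Morlet center-frequency parameter (dimensionless; default 5,
#'   about five cycles per atom).
#' @return list of class `epoch_config`.
#' @export
epoch_config <- function(fs = 586, window = 1, step = 0.1,
                         freqs = seq(10, 150, by = 10), n_time_bins = 10L,
                         omega0 = 5) {
  if (fs <= 0 || window <= 0 || step <= 0) stop("fs/window/step must be > 0")
  if (any(diff(freqs) <= 0) || any(freqs <= 0))
    stop("`freqs` must be strictly increasing and positive")
  if (max(freqs) >= fs / 2)
    stop("analysis frequencies must be below the Nyquist frequency ", fs / 2)
  n_time_bins <- as.integer(n_time_bins)
  if (round(window * fs) < n_time_bins)
    stop("window too short for ", n_time_bins, " temporal bins")
  structure(list(fs = fs, window = window, step = step, freqs = freqs,
                 n_time_bins = n_time_bins, omega0 = omega0),
            class = "epoch_config")
}

#' Cut a multichannel signal into sliding epochs
#'
#' Epochs of `round(window * fs)` samples start every `round(step * fs)`
#' samples; each epoch is timestamped by its *end* sample so that features
#' are causal (an epoch only uses signal up to its timestamp).
#'
#' @param signal numeric matrix, time x channels.
#' @param cfg [epoch_config()].
#' @return list with `epochs` (list of sample x channel matrices) and
#'   `end_sample` (integer vector); empty (with a warning) when the signal
#'   is shorter than one window.
#' @export
segment_stream <- function(signal, cfg = epoch_config()) {
  signal <- as.matrix(signal)
  wlen <- round(cfg$window * cfg$fs)
  slen <- round(cfg$step * cfg$fs)
  n <- nrow(signal)
  if (n < wlen) {
    warning("signal shorter than one epoch window; returning no epochs")
    return(list(epochs = list(), end_sample = integer(0)))
  }
  starts <- seq.int(1L, n - wlen + 1L, by = slen)
  list(
    epochs = lapply(starts, function(s) signal[s:(s + wlen - 1L), , drop = FALSE]),
    end_sample = as.integer(starts + wlen - 1L)
  )
}

# Complex Morlet atom sampled at the given analysis frequency. The scale is
# s = omega0 * fs / (2 pi f0) samples, so the atom's oscillation matches f0;
# support truncated at +/- 4 s. L2-normalized per scale (1/sqrt(s)) so that
# magnitudes are comparable across frequencies.
morlet_atom <- function(f0, fs, omega0 = 5) {
  s <- omega0 * fs / (2 * pi * f0)
  half <- ceiling(4 * s)
  tk <- seq.int(-half, half) / s
  pi^(-0.25) * exp(1i * omega0 * tk) * exp(-tk^2 / 2) / sqrt(s)
}

# FFT-based "same" convolution of each signal column with a complex kernel.
convolve_same <- function(x, kernel) {
  n <- nrow(x); m <- length(kernel)
  nfft <- stats::nextn(n + m - 1L, 2L)
  kf <- stats::fft(c(kernel, complex(real = rep(0, nfft - m))))
  half <- (m - 1L) %/% 2L
  out <- matrix(0 + 0i, n, ncol(x))
  for (j in seq_len(ncol(x))) {
    xf <- stats::fft(c(x[, j], rep(0, nfft - n)))
    full <- stats::fft(xf * kf, inverse = TRUE) / nfft
    out[, j] <- full[(half + 1L):(half + n)]
  }
  out
}

#' Morlet time-frequency magnitude of one epoch
#'
#' Magnitude of the complex Morlet transform at every configured frequency.
#' The transform is computed on the epoch alone, without padding context,
#' matching the causal online constraint.
#'
#' @param epoch numeric matrix, samples x channels.
#' @param cfg [epoch_config()].
#' @return nonnegative order-3 array, samples x frequencies x channels.
#' @export
morlet_tfr <- function(epoch, cfg = epoch_config()) {
  epoch <- as.matrix(epoch)
  n <- nrow(epoch); nc <- ncol(epoch); nf <- length(cfg$freqs)
  out <- array(0, dim = c(n, nf, nc))
  for (k in seq_len(nf)) {
    atom <- morlet_atom(cfg$freqs[k], cfg$fs, cfg$omega0)
    out[, k, ] <- Mod(convolve_same(epoch, atom))
  }
  out
}

# Contiguous near-equal bin memberships: the remainder goes to the leading
# bins (586 samples into 10 bins -> 59,59,59,59,59,59,58,58,58,58).
time_bin_index <- function(n_samples, n_bins) {
  base <- n_samples %/% n_bins
  rem <- n_samples %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  rep(seq_len(n_bins), times = sizes)
}

#' Feature tensor of one epoch
#'
#' Morlet magnitudes averaged within `n_time_bins` contiguous temporal bins.
#'
#' @param epoch numeric matrix, samples x channels.
#' @param cfg [epoch_config()].
#' @return order-3 array (class `tensor3`),
#'   `n_time_bins` x `length(freqs)` x channels.
#' @export
epoch_to_feature_tensor <- function(epoch, cfg = epoch_config()) {
  tfr <- morlet_tfr(epoch, cfg)
  n <- dim(tfr)[1]; nf <- dim(tfr)[2]; nc <- dim(tfr)[3]
  bins <- time_bin_index(n, cfg$n_time_bins)
  out <- array(0, dim = c(cfg$n_time_bins, nf, nc))
  for (b in seq_len(cfg$n_time_bins)) {
    sel <- bins == b
    out[b, , ] <- colMeans(tfr[sel, , , drop = FALSE], dims = 1)
  }
  tensor3(out, dim(out))
}

#' Tensorize a whole multichannel stream
#'
#' Convenience wrapper: [segment_stream()] then [epoch_to_feature_tensor()]
#' per epoch, stacked into an order-4 block.
#'
#' @param signal numeric matrix, time x channels.
#' @param cfg [epoch_config()].
#' @return list with `X` (epochs x n_time_bins x freqs x channels array) and
#'   `end_sample`.
#' @export
tensorize_stream <- function(signal, cfg = epoch_config()) {
  seg <- segment_stream(signal, cfg)
  ne <- length(seg$epochs)
  if (ne == 0L) return(list(X = NULL, end_sample = integer(0)))
  nc <- ncol(as.matrix(signal))
  X <- array(0, dim = c(ne, cfg$n_time_bins, length(cfg$freqs), nc))
  for (i in seq_len(ne))
    X[i, , , ] <- epoch_to_feature_tensor(seg$epochs[[i]], cfg)
  list(X = X, end_sample = seg$end_sample)
}
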