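## Full-record FFT magnitude of a session, averaged over channels and
## bin-averaged onto a 1 Hz grid.  The FFT is computed at an FFT-friendly
## zero-padded length; magnitudes are normalized by the true sample count
## so that sessions of different lengths are comparable.
session_mean_spectrum <- function(session, grid_hz = 1) {
  stopifnot(inherits(session, "emg_session"))
  n <- ncol(session$samples)
  fs <- session$sampling_rate
  m <- stats::nextn(n, c(2, 3, 5))
  acc <- NULL
  for (ch in seq_len(nrow(session$samples))) {
    x <- c(session$samples[ch, ], numeric(m - n))
    X <- abs(stats::fft(x))[seq_len(m %/% 2 + 1L)] / n
    acc <- if (is.null(acc)) X else acc + X
  }
  acc <- acc / nrow(session$samples)
  freq <- (seq_len(m %/% 2 + 1L) - 1) * fs / m
  centers <- seq(0, floor(fs / 2), by = grid_hz)
  bin <- findInterval(freq, centers - grid_hz / 2)
  keep <- bin >= 1 & bin <= length(centers)
  amp <- as.numeric(tapply(acc[keep], bin[keep], mean))
  idx <- sort(unique(bin[keep]))
  list(frequency = centers[idx], amplitude = amp)
}

## Least-squares fit of a scaled binomial probability-mass envelope
## counts[i] ~ s * dbinom(i - 1, n_bins - 1, p), i = 1..n_bins.
fit_binomial_envelope <- function(counts) {
  nb <- length(counts)
  sse_for <- function(p) {
    b <- stats::dbinom(0:(nb - 1), nb - 1, p)
    s <- sum(counts * b) / sum(b * b)
    sum((counts - s * b)^2)
  }
  pgrid <- seq(0.002, 0.998, by = 0.002)
  p0 <- pgrid[which.min(vapply(pgrid, sse_for, numeric(1)))]
  opt <- stats::optimize(sse_for, c(max(0.001, p0 - 0.002),
                                    min(0.999, p0 + 0.002)))
  p <- opt$minimum
  b <- stats::dbinom(0:(nb - 1), nb - 1, p)
  s <- sum(counts * b) / sum(b * b)
  fitted <- s * b
  list(p = p, scale = s, fitted = fitted,
       sigma = sqrt(mean((counts - fitted)^2)))
}

#' Frequency cut-off from an averaged amplitude spectrum
#'
#' Implements the histogram heuristic on a precomputed averaged spectrum:
#' build an amplitude-wise histogram of the frequency bins, fit a scaled
#' binomial probability-mass envelope to the bin counts by least squares,
#' scan the bins from low to high amplitude for the first count that
#' deviates from the envelope by more than the fit's RMS residual (the
#' envelope "standard deviation"), take that bin's centre as the amplitude
#' threshold, and return the highest frequency whose averaged amplitude
#' reaches the threshold as the cut-off.
#'
#' @param frequency Frequencies (Hz) of the averaged spectrum.
#' @param amplitude Averaged FFT magnitudes, same length.
#' @param n_bins Number of amplitude histogram bins.
#' @return An object of class `cutoff_result`; see [compute_cutoff()].
#' @export
cutoff_from_spectrum <- function(frequency, amplitude, n_bins = 50) {
  stopifnot(length(frequency) == length(amplitude), length(amplitude) >= 2)
  if (any(!is.finite(amplitude)) || any(amplitude < 0))
    stopf("amplitudes must be finite and nonnegative")
  if (max(amplitude) <= min(amplitude))
    stopf("histogram not informative: all averaged amplitudes are equal")
  breaks <- seq(0, max(amplitude) * (1 + 1e-12), length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  counts <- as.numeric(table(cut(amplitude, breaks, include.lowest = TRUE)))
  env <- fit_binomial_envelope(counts)
  dev <- abs(counts - env$fitted)
  out <- which(dev > env$sigma)
  if (!length(out))
    stopf("histogram not informative: no outlier beyond the envelope residual")
  amplitude_threshold <- mids[out[1]]
  reach <- amplitude >= amplitude_threshold
  if (!any(reach))
    stopf("histogram not informative: no frequency reaches the threshold")
  structure(
    list(cutoff_frequency = max(frequency[reach]),
         amplitude_threshold = amplitude_threshold,
         histogram = list(breaks = breaks, mids = mids, counts = counts),
         envelope = env,
         spectrum = list(frequency = frequency, amplitude = amplitude)),
    class = "cutoff_result")
}

#' Data-driven frequency cut-off for the activation feature
#'
#' Averages full-record FFT magnitude spectra over channels and sessions
#' onto a common 1 Hz grid and applies the amplitude-histogram heuristic of
#' [cutoff_from_spectrum()].  The heuristic exploits the fact that
#' high-amplitude frequencies are a minority of the spectrum: the first
#' histogram bin that escapes the fitted envelope marks the amplitude
#' threshold, and the highest frequency still reaching that threshold is
#' the cut-off point for further analysis.
#'
#' @param sessions One `emg_session` or a list of them (sampling rates must
#'   agree).
#' @param n_bins Number of amplitude histogram bins.
#' @return An object of class `cutoff_result` with fields
#'   `cutoff_frequency` (Hz), `amplitude_threshold`, `histogram`,
#'   `envelope` (fit parameters and RMS residual `sigma`) and the averaged
#'   `spectrum`.
#' @export
compute_cutoff <- function(sessions, n_bins = 50) {
  if (inherits(sessions, "emg_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1L)
  fs <- unique(vapply(sessions, function(s) s$sampling_rate, numeric(1)))
  if (length(fs) != 1L)
    stopf("sessions must share one sampling rate")
  specs <- lapply(sessions, session_mean_spectrum)
  freq <- specs[[1]]$frequency
  for (sp in specs)
    if (length(sp$frequency) != length(freq))
      stopf("sessions produced incompatible frequency grids")
  amp <- Reduce(`+`, lapply(specs, `[[`, "amplitude")) / length(specs)
  cutoff_from_spectrum(freq, amp, n_bins = n_bins)
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> cutoff %.1f Hz (amplitude threshold %.3g)\n",
              x$cutoff_frequency, x$amplitude_threshold))
  invisible(x)
}
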