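#' Short-time Fourier magnitude spectrogram of one channel
#'
#' Frames the signal with a Hann window and returns one-sided FFT
#' magnitudes.  Frame times are window centres; frequency bins span
#' `[0, Nyquist]`.
#'
#' @param x Numeric samples of one channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param window_s Window length in seconds (Hann).
#' @param hop_s Hop between window starts in seconds; `0 < hop_s <= window_s`.
#' @return An object of class `emg_spectrogram`: `magnitudes`
#'   (`frequency bins x frames`), `frequencies` (Hz), `frame_times` (s),
#'   plus window metadata.
#' @export
compute_spectrogram <- function(x, sampling_rate, window_s = 0.25,
                                hop_s = 0.125) {
  if (length(x) == 0L) stopf("empty signal")
  if (any(!is.finite(x))) stopf("non-finite samples")
  assert_scalar_num(sampling_rate, "sampling_rate")
  assert_scalar_num(window_s, "window_s")
  assert_scalar_num(hop_s, "hop_s")
  if (hop_s <= 0 || hop_s > window_s)
    stopf("`hop_s` must satisfy 0 < hop_s <= window_s")
  nwin <- round(window_s * sampling_rate)
  hop <- max(1L, round(hop_s * sampling_rate))
  if (length(x) < nwin)
    stopf("signal shorter than one window (%d < %d samples)", length(x), nwin)

  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1)))
  idx <- outer(seq_len(nwin) - 1L, starts, "+")
  frames <- matrix(x[idx], nrow = nwin) * w
  nb <- nwin %/% 2 + 1L
  mag <- abs(stats::mvfft(frames))[seq_len(nb), , drop = FALSE]

  structure(
    list(magnitudes = mag,
         frequencies = (seq_len(nb) - 1) * sampling_rate / nwin,
         frame_times = (starts - 1 + (nwin - 1) / 2) / sampling_rate,
         window_s = window_s,
         hop_s = hop_s,
         window = "hann",
         sampling_rate = sampling_rate),
    class = "emg_spectrogram")
}

#' @export
print.emg_spectrogram <- function(x, ...) {
  cat(sprintf("<emg_spectrogram> %d bins x %d frames, window %gs hop %gs\n",
              nrow(x$magnitudes), ncol(x$magnitudes), x$window_s, x$hop_s))
  invisible(x)
}

#' Summed muscle-activity trace
#'
#' Sums spectrogram magnitudes over channels and then over frequencies,
#' yielding one activity value per time frame, and attaches an SNR-based
#' detection threshold of the form `rest mean + k_sigma * rest sd`.  The
#' rest statistics are estimated from the lower tail of the trace (the
#' 5th and 25th percentiles, calibrated against a Gaussian rest bulk:
#' `sigma_hat = (q25 - q05) / 0.9706`, `mu_hat = q25 + 0.674 * sigma_hat`),
#' which stays anchored in the rest distribution for any in-trial duty
#' cycle up to about two thirds of the session.
#'
#' @param spectrograms List of `emg_spectrogram`s on identical grids.
#' @param k_sigma Threshold multiplier (default 3).
#' @return An object of class `activity_trace`: `values`, `frame_times`,
#'   `snr_threshold`.
#' @export
summed_activity <- function(spectrograms, k_sigma = 3) {
  if (inherits(spectrograms, "emg_spectrogram"))
    spectrograms <- list(spectrograms)
  stopifnot(length(spectrograms) >= 1L)
  ref <- spectrograms[[1]]
  for (sg in spectrograms) {
    stopifnot(inherits(sg, "emg_spectrogram"))
    if (!isTRUE(all.equal(sg$frequencies, ref$frequencies)) ||
        !isTRUE(all.equal(sg$frame_times, ref$frame_times)))
      stopf("spectrograms must share frequency and time grids")
  }
  values <- Reduce(`+`, lapply(spectrograms, function(sg) colSums(sg$magnitudes)))
  q <- stats::quantile(values, c(0.05, 0.25), names = FALSE)
  sigma_hat <- (q[2] - q[1]) / 0.9706   # Gaussian q25 - q05 spread
  mu_hat <- q[2] + 0.674 * sigma_hat    # Gaussian q25 offset from the mean
  thr <- mu_hat + k_sigma * sigma_hat
  if (!is.finite(thr)) thr <- q[2]
  structure(
    list(values = values,
         frame_times = ref$frame_times,
         snr_threshold = thr,
         k_sigma = k_sigma),
    class = "activity_trace")
}

#' Mark activity events on a trace
#'
#' Returns the frame times at which the activity trace strictly exceeds its
#' SNR threshold, in increasing order.  May be empty.
#'
#' @param trace An [summed_activity()] trace.
#' @return Numeric vector of event times in seconds.
#' @export
detect_activity_events <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  if (length(trace$values) == 0L) stopf("empty trace")
  trace$frame_times[trace$values > trace$snr_threshold]
}

## Exact 1-D K-means by dynamic programming: for sorted 1-D data the
## optimal within-sum-of-squares partition is contiguous, so the global
## optimum is found in O(k n^2) with prefix sums.  Returns cluster labels
## (1..k, in sorted-data order).
kmeans_1d <- function(x, k) {
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  segcost <- function(i, j) {  # within-SS of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (i in 1:n) D[1, i] <- segcost(1, i)
  if (k > 1) for (q in 2:k) for (i in q:n) {
    for (j in q:i) {
      c_ <- D[q - 1, j - 1] + segcost(j, i)
      if (c_ < D[q, i]) { D[q, i] <- c_; B[q, i] <- j }
    }
  }
  labels <- integer(n)
  i <- n
  for (q in k:1) {
    j <- if (q > 1) B[q, i] else 1L
    labels[j:i] <- q
    i <- j - 1L
  }
  labels
}

#' Localize contraction trials from activity events
#'
#' Clusters activity-event times into `n_trials` groups with exact 1-D
#' K-means (dynamic programming over the sorted events, which always finds
#' the global within-sum-of-squares optimum and is deterministic) and
#' takes each cluster's median event time as the trial origin, refined by
#' one trimmed pass that discards events farther than `half_width` from
#' the cluster median (such events cannot belong to the trial).  Trial
#' onset and offset are the origin -/+ `half_width` seconds.
#'
#' @param events Activity-event times in seconds.
#' @param n_trials Number of trials to localize.
#' @param seed Kept for interface stability; the exact solver is
#'   deterministic and does not consume randomness.
#' @param half_width Half trial duration in seconds (default 2.5).
#' @return A `trial_segments` data frame with columns `origin`, `onset`,
#'   `offset`, `cluster`, sorted by origin.
#' @export
localize_trials <- function(events, n_trials, seed = 1L, half_width = 2.5) {
  if (length(events) < n_trials)
    stopf("insufficient activity events: %d < %d trials",
          length(events), n_trials)
  events <- sort(as.numeric(events))
  if (length(unique(events)) < n_trials)
    stopf("insufficient activity events: fewer than %d distinct times",
          n_trials)
  labels <- kmeans_1d(events, n_trials)
  origins <- vapply(seq_len(n_trials), function(q) {
    ev <- events[labels == q]
    med <- stats::median(ev)
    stats::median(ev[abs(ev - med) <= half_width])
  }, numeric(1))
  ord <- order(origins)
  seg <- data.frame(origin = origins[ord],
                    onset = origins[ord] - half_width,
                    offset = origins[ord] + half_width,
                    cluster = seq_len(n_trials)[ord])
  if (any(seg$onset < 0))
    stopf("trial onset before recording start (origin %.2f s)",
          seg$origin[which(seg$onset < 0)[1]])
  if (nrow(seg) > 1 && any(diff(seg$origin) < 2 * half_width))
    stopf("overlapping trial segments: origins closer than %g s",
          2 * half_width)
  class(seg) <- c("trial_segments", "data.frame")
  seg
}
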