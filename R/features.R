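#' Per-muscle trial spectra
#'
#' For each localized trial segment and each muscle, computes the one-sided
#' FFT magnitude of that muscle's samples over `[onset, offset]`.
#'
#' @param session An `emg_session`.
#' @param segments A `trial_segments` frame from [localize_trials()].
#' @return An object of class `trial_spectra`: `segments`, `frequencies`
#'   (Hz) and `v`, an array `[frequency bins x muscles x trials]` of
#'   magnitudes.
#' @export
trial_spectra <- function(session, segments) {
  stopifnot(inherits(session, "emg_session"),
            inherits(segments, "trial_segments"))
  fs <- session$sampling_rate
  n <- ncol(session$samples)
  i0 <- round(segments$onset * fs) + 1L
  i1 <- round(segments$offset * fs)
  if (any(i0 < 1L) || any(i1 > n))
    stopf("trial segment exceeds recording bounds [0, %.2f s]", n / fs)
  nseg <- i1[1] - i0[1] + 1L
  nb <- nseg %/% 2 + 1L
  v <- array(0, dim = c(nb, nrow(session$samples), nrow(segments)),
             dimnames = list(NULL, session$channel_names, NULL))
  for (k in seq_len(nrow(segments))) {
    seg <- session$samples[, i0[k]:i1[k], drop = FALSE]
    v[, , k] <- abs(stats::mvfft(t(seg)))[seq_len(nb), , drop = FALSE]
  }
  structure(
    list(segments = segments,
         frequencies = (seq_len(nb) - 1) * fs / nseg,
         v = v),
    class = "trial_spectra")
}

#' Frequency-weighted activation feature
#'
#' The scalar activation feature of one trial spectrum: the sum of
#' `f * v(f)` over frequency bins between `band_low` and the cut-off
#' frequency.  Higher motor-unit recruitment shifts spectral amplitude
#' upward in both magnitude and frequency, which this weighted sum tracks.
#'
#' @param v Spectrum: a list or data frame with elements `frequency` (Hz)
#'   and `amplitude` (nonnegative magnitudes).
#' @param cutoff A [compute_cutoff()] result, or a cut-off frequency in Hz.
#' @param band_low Lower summation limit in Hz (the recording bandwidth
#'   floor).
#' @return Nonnegative scalar feature `F` in arbitrary units.
#' @export
activation_feature <- function(v, cutoff, band_low = 20) {
  f <- v$frequency
  a <- v$amplitude
  stopifnot(length(f) == length(a))
  if (any(!is.finite(a)) || any(a < 0))
    stopf("spectrum amplitudes must be finite and nonnegative")
  fc <- if (inherits(cutoff, "cutoff_result")) cutoff$cutoff_frequency
        else as.numeric(cutoff)
  if (band_low >= fc)
    stopf("empty frequency range: band_low (%g) >= cutoff (%g)", band_low, fc)
  sel <- f >= band_low & f <= fc
  if (!any(sel)) stopf("empty frequency range: no bins in [%g, %g] Hz",
                       band_low, fc)
  sum(f[sel] * a[sel])
}

#' Normalize raw activation features to [0, 1]
#'
#' Scales the per-muscle features so the largest becomes 1 (default), which
#' guarantees activations admissible for the simulated muscles.
#' `method = "rf"` instead normalizes to the RF channel (the voluntarily
#' maximally activated muscle in the study protocol); values above 1 are
#' then clipped with a warning, since RF is not guaranteed maximal.
#'
#' @param features Named nonnegative features per muscle (canonical order
#'   or named by muscle), at least one positive.
#' @param method `"max"` or `"rf"`.
#' @return An object of class `activation_vector`: named numeric in
#'   `[0, 1]` over the canonical muscles, with attributes `raw` (the input
#'   features), `reference` (normalization reference used) and `clipped`
#'   (count of clipped values).
#' @export
normalize_activations <- function(features, method = c("max", "rf")) {
  method <- match.arg(method)
  if (is.null(names(features))) names(features) <- knee_muscles
  if (!setequal(names(features), knee_muscles))
    stopf("`features` must cover the 7 canonical muscles")
  features <- features[knee_muscles]
  if (any(!is.finite(features)) || any(features < 0))
    stopf("features must be finite and nonnegative")
  if (all(features == 0)) stopf("no muscle activity: all features are zero")
  ref <- switch(method,
                max = max(features),
                rf = features[["RF"]])
  if (ref <= 0) stopf("normalization reference is zero (method %s)", method)
  a <- features / ref
  clipped <- sum(a > 1)
  if (clipped > 0) {
    warning(sprintf("%d activation(s) clipped to 1 (method %s)",
                    clipped, method))
    a <- pmin(a, 1)
  }
  structure(a, class = "activation_vector", raw = features,
            reference = method, clipped = clipped)
}

#' @export
print.activation_vector <- function(x, ...) {
  cat("<activation_vector>\n")
  print(round(unclass(x)[seq_along(x)], 4))
  invisible(x)
}
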