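## Band-limited Gaussian noise of unit variance, synthesized spectrally.
## Draws from the current RNG stream.  The spectrum is built at an
## FFT-friendly length and truncated to `n`, which leaves the process
## stationary and strictly confined to `band`.
band_noise <- function(n, sampling_rate, band) {
  m <- stats::nextn(n, c(2, 3, 5))
  freq <- (seq_len(m) - 1) / m * sampling_rate
  fpos <- pmin(freq, sampling_rate - freq)
  half <- seq_len(m %/% 2 + 1L)               # non-negative frequencies
  inband <- half[fpos[half] >= band[1] & fpos[half] <= band[2] & half > 1L &
                   half != m %/% 2 + 1L]
  nb <- length(inband)
  X <- complex(length.out = m)
  X[inband] <- complex(real = stats::rnorm(nb), imaginary = stats::rnorm(nb))
  X[m - inband + 2L] <- Conj(X[inband])
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  x / (2 * sqrt(nb))                          # unit variance
}

## Raised-cosine on/off envelope for one trial burst, on the session time
## grid.  `ramp` seconds of cosine taper at onset and offset.
trial_envelope <- function(t, center, duration, ramp = 0.25) {
  onset <- center - duration / 2
  offset <- center + duration / 2
  env <- numeric(length(t))
  inside <- t >= onset & t <= offset
  u <- t[inside]
  e <- rep(1, length(u))
  up <- u < onset + ramp
  e[up] <- 0.5 * (1 - cos(pi * (u[up] - onset) / ramp))
  down <- u > offset - ramp
  e[down] <- 0.5 * (1 - cos(pi * (offset - u[down]) / ramp))
  env[inside] <- e
  env
}

#' Generate a synthetic surface-EMG session
#'
#' Emulates one isometric knee-extension recording session.  Each channel
#' carries band-limited Gaussian noise (confined to the protocol band)
#' whose amplitude is modulated by a raised-cosine burst envelope during
#' contraction trials, scaled by the muscle's profile amplitude at the
#' session's knee angle; outside trials only the noise floor remains.
#' Rest is placed before the first and after the last trial so that trial
#' detection cannot succeed by assuming trials start at time zero.  Trial
#' centres are jittered by a truncated Gaussian so that the localization
#' stage's median-origin step is exercised.
#'
#' The returned session carries full ground truth (trial centre times and
#' per-trial per-muscle amplitudes), which downstream stages may use for
#' validation but never for inference.
#'
#' @param protocol An [emg_protocol()].
#' @param profile An [activation_profile()].
#' @param seed Integer seed; identical `(seed, protocol, profile)` give
#'   bit-identical sessions.
#' @param trial_scale Optional per-trial amplitude scalings: either a
#'   numeric vector of length `n_trials` (applied to every muscle) or a
#'   `7 x n_trials` matrix with muscle rows, e.g. to emulate a trial in
#'   which the task muscles were driven at sub-maximal effort.  Note that
#'   per-trial max-normalization downstream removes any *uniform* scaling;
#'   only scalings that change the balance between muscles are observable
#'   after normalization.
#' @param subject_id Optional subject label stored in the session.
#' @return An object of class `emg_session`: a list with `samples`
#'   (`channels x time` matrix in arbitrary voltage units), `sampling_rate`,
#'   `channel_names`, `knee_angle`, `subject_id` and `ground_truth`.
#' @export
generate_session <- function(protocol, profile, seed,
                             trial_scale = NULL, subject_id = NULL) {
  stopifnot(inherits(protocol, "emg_protocol"),
            inherits(profile, "emg_profile"))
  assert_scalar_num(seed, "seed")
  nt <- protocol$n_trials
  td <- protocol$trial_duration
  rd <- protocol$rest_duration
  fs <- protocol$sampling_rate
  if (is.null(trial_scale)) trial_scale <- rep(1, nt)
  if (is.matrix(trial_scale)) {
    if (nrow(trial_scale) != 7L || ncol(trial_scale) != nt)
      stopf("`trial_scale` matrix must be 7 muscles x %d trials", nt)
    if (!is.null(rownames(trial_scale)))
      trial_scale <- trial_scale[protocol$muscles, , drop = FALSE]
  } else {
    if (length(trial_scale) != nt)
      stopf("`trial_scale` must have %d values", nt)
    trial_scale <- matrix(trial_scale, nrow = 7L, ncol = nt, byrow = TRUE)
  }
  if (any(!is.finite(trial_scale)) || any(trial_scale < 0))
    stopf("`trial_scale` must be nonnegative finite values")
  ## Jitter is truncated at 3 sd; trial windows must stay disjoint after it.
  jmax <- 3 * profile$trial_jitter
  if (nt > 1 && rd <= 2 * jmax)
    stopf(paste0("rest_duration (%g s) too short: trial windows can overlap ",
                 "after +/-%g s of jitter"), rd, jmax)

  duration <- nt * td + (nt + 1) * rd
  n <- round(duration * fs)
  tgrid <- (seq_len(n) - 1) / fs
  amps <- profile_amplitude(profile, protocol$knee_angle)
  if (any(!is.finite(amps))) stopf("non-finite profile amplitudes")

  with_seed(seed, {
    centers0 <- rd * seq_len(nt) + td * (seq_len(nt) - 1) + td / 2
    jit <- stats::rnorm(nt, 0, profile$trial_jitter)
    jit <- pmin(pmax(jit, -jmax), jmax)
    centers <- centers0 + jit

    ## per-trial envelope support (trials are disjoint by construction)
    windows <- lapply(seq_len(nt), function(k) {
      idx <- which(abs(tgrid - centers[k]) <= td / 2)
      list(idx = idx, env = trial_envelope(tgrid[idx], centers[k], td))
    })

    samples <- matrix(0, nrow = 7L, ncol = n,
                      dimnames = list(protocol$muscles, NULL))
    for (m in seq_len(7L)) {
      carrier <- band_noise(n, fs, protocol$band)
      gain <- rep(profile$noise_floor, n)
      for (k in seq_len(nt))
        gain[windows[[k]]$idx] <- gain[windows[[k]]$idx] +
          amps[m] * trial_scale[m, k] * windows[[k]]$env
      samples[m, ] <- carrier * gain
    }

    structure(
      list(samples = samples,
           sampling_rate = fs,
           channel_names = protocol$muscles,
           knee_angle = protocol$knee_angle,
           subject_id = subject_id,
           ground_truth = list(
             trial_centers = centers,
             amplitudes = trial_scale * amps,
             noise_floor = profile$noise_floor)),
      class = "emg_session")
  })
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("<emg_session> %d channels x %d samples (%.1f s at %g Hz), knee %g deg\n",
              nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$sampling_rate, x$sampling_rate,
              x$knee_angle))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: %d trial centres\n",
                length(x$ground_truth$trial_centers)))
  invisible(x)
}

#' Write a session to CSV plus JSON sidecar
#'
#' The CSV holds a `time_s` column and one column per channel; the sidecar
#' `<name>.meta.json` holds sampling rate, knee angle, subject id and
#' ground truth (if any).
#'
#' @param session An `emg_session`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "emg_session"))
  n <- ncol(session$samples)
  dt <- data.table::data.table(time_s = (seq_len(n) - 1) / session$sampling_rate)
  for (ch in session$channel_names)
    data.table::set(dt, j = ch, value = session$samples[ch, ])
  data.table::fwrite(dt, path)
  meta <- list(
    sampling_rate = session$sampling_rate,
    knee_angle_deg = session$knee_angle,
    subject_id = session$subject_id,
    channel_names = session$channel_names,
    ground_truth = session$ground_truth)
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

meta_path <- function(path) {
  paste0(sub("\\.csv$", "", path), ".meta.json")
}

#' Read a session written by [write_session()]
#'
#' Channels are matched by name and reordered to the canonical muscle list;
#' a missing canonical channel, a malformed header or a non-monotonic time
#' column raise descriptive errors.
#'
#' @param path CSV file path.
#' @return An `emg_session`.
#' @export
read_session <- function(path) {
  dt <- data.table::fread(path)
  if (ncol(dt) < 2L || names(dt)[1] != "time_s")
    stopf("malformed header in %s: first column must be `time_s`", path)
  tvec <- dt[["time_s"]]
  if (any(!is.finite(tvec)) || is.unsorted(tvec, strictly = TRUE))
    stopf("non-monotonic time column in %s", path)
  chans <- setdiff(names(dt), "time_s")
  missing <- setdiff(knee_muscles, chans)
  if (length(missing))
    stopf("missing channel(s) in %s: %s", path, paste(missing, collapse = ", "))
  extra <- setdiff(chans, knee_muscles)
  if (length(extra))
    stopf("unknown channel(s) in %s: %s", path, paste(extra, collapse = ", "))

  mp <- meta_path(path)
  meta <- if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = TRUE)
          else list()
  fs <- meta$sampling_rate
  fs <- if (is.null(fs)) 1 / stats::median(diff(tvec)) else as.numeric(fs)
  gt <- meta$ground_truth
  if (!is.null(gt)) {
    if (!is.null(gt$amplitudes))
      gt$amplitudes <- as.matrix(gt$amplitudes)
    if (!is.null(gt$trial_centers))
      gt$trial_centers <- as.numeric(gt$trial_centers)
  }

  samples <- t(as.matrix(dt[, knee_muscles, with = FALSE]))
  rownames(samples) <- knee_muscles
  structure(
    list(samples = samples,
         sampling_rate = fs,
         channel_names = knee_muscles,
         knee_angle = if (is.null(meta$knee_angle_deg)) NA_real_
                      else as.numeric(meta$knee_angle_deg),
         subject_id = meta$subject_id,
         ground_truth = gt),
    class = "emg_session")
}
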