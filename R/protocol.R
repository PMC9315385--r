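#' Recording protocol for an isometric knee-extension session
#'
#' Describes one EMG recording session: repeated maximal isometric
#' contractions at a fixed knee angle, separated by long rests.  Defaults
#' follow the study protocol the package emulates: 6 contractions of 5 s
#' with 3-min rests, 7 channels sampled at 1.9 kHz with a 20-450 Hz
#' recording bandwidth, at one of the knee angles 0, 20, 60 or 90 degrees.
#'
#' @param n_trials Number of contractions per session.
#' @param trial_duration Contraction duration in seconds.
#' @param rest_duration Rest duration in seconds.  Rest is also placed
#'   before the first and after the last contraction, so the session
#'   duration is `n_trials * trial_duration + (n_trials + 1) * rest_duration`.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Recording bandwidth `c(low, high)` in Hz.
#' @param knee_angle Knee flexion angle in degrees (0 = fully extended).
#' @param muscles Ordered channel names; must be the 7 canonical muscles.
#' @return An object of class `emg_protocol`.
#' @seealso [activation_profile()], [generate_session()]
#' @export
emg_protocol <- function(n_trials = 6L,
                         trial_duration = 5,
                         rest_duration = 180,
                         sampling_rate = 1900,
                         band = c(20, 450),
                         knee_angle = 60,
                         muscles = knee_muscles) {
  assert_scalar_num(n_trials, "n_trials", lower = 1)
  assert_scalar_num(trial_duration, "trial_duration")
  if (trial_duration <= 0) stopf("`trial_duration` must be > 0")
  assert_scalar_num(rest_duration, "rest_duration", lower = 0)
  assert_scalar_num(sampling_rate, "sampling_rate")
  if (!is.numeric(band) || length(band) != 2L || any(!is.finite(band)))
    stopf("`band` must be c(low, high) in Hz")
  if (!(0 < band[1] && band[1] < band[2] && band[2] < sampling_rate / 2))
    stopf("`band` must satisfy 0 < low < high < sampling_rate/2")
  assert_scalar_num(knee_angle, "knee_angle", lower = 0, upper = 120)
  if (length(muscles) != 7L || anyDuplicated(muscles) > 0L)
    stopf("`muscles` must be 7 unique channel names")
  structure(
    list(n_trials = as.integer(n_trials),
         trial_duration = trial_duration,
         rest_duration = rest_duration,
         sampling_rate = sampling_rate,
         band = as.numeric(band),
         knee_angle = knee_angle,
         muscles = as.character(muscles)),
    class = "emg_protocol")
}

#' @export
print.emg_protocol <- function(x, ...) {
  cat(sprintf(
    "<emg_protocol> %d x %.3gs trials, %.3gs rests, %g Hz, band %g-%g Hz, knee %g deg\n",
    x$n_trials, x$trial_duration, x$rest_duration, x$sampling_rate,
    x$band[1], x$band[2], x$knee_angle))
  invisible(x)
}

## Default per-muscle activation amplitudes over the four study angles.
## Quadriceps amplitudes fall strictly with knee angle while Se and TA rise
## weakly; VM leads the quadriceps.  See the methods vignette for rationale.
default_profile_amplitudes <- function() {
  angles <- c(0, 20, 60, 90)
  amp <- rbind(
    RF = c(0.88, 0.72, 0.45, 0.26),
    VL = c(0.90, 0.75, 0.50, 0.30),
    VM = c(0.95, 0.80, 0.55, 0.35),
    Se = c(0.14, 0.19, 0.30, 0.37),
    BF = c(0.15, 0.17, 0.21, 0.24),
    MG = c(0.20, 0.20, 0.20, 0.20),
    TA = c(0.08, 0.13, 0.22, 0.33))
  colnames(amp) <- angles
  amp
}

#' Per-muscle activation amplitude profile
#'
#' Maps knee angle to the mean contraction amplitude of each muscle, on the
#' generator's arbitrary full-scale unit.  The default profile encodes the
#' empirical sign structure of isometric knee extension: quadriceps
#' amplitudes (RF, VL, VM) decrease strictly with knee flexion angle while
#' Se and TA increase weakly.  Amplitudes at angles between the tabulated
#' ones are linearly interpolated.
#'
#' @param amplitudes Numeric matrix `[7 muscles x angles]`, rownames the
#'   canonical muscles, colnames the knee angles in degrees, all values in
#'   `[0, 1]`.
#' @param noise_floor Baseline noise amplitude relative to full scale.
#' @param trial_jitter Standard deviation (s) of trial-centre timing jitter.
#' @return An object of class `emg_profile`.
#' @export
activation_profile <- function(amplitudes = default_profile_amplitudes(),
                               noise_floor = 0.05,
                               trial_jitter = 0.5) {
  if (!is.matrix(amplitudes) || is.null(rownames(amplitudes)) ||
      is.null(colnames(amplitudes)))
    stopf("`amplitudes` must be a matrix with muscle rownames and angle colnames")
  if (!setequal(rownames(amplitudes), knee_muscles))
    stopf("`amplitudes` rownames must be the 7 canonical muscles")
  if (any(!is.finite(amplitudes)))
    stopf("`amplitudes` must be finite")
  if (any(amplitudes < 0 | amplitudes > 1))
    stopf("`amplitudes` must lie in [0, 1]")
  angles <- as.numeric(colnames(amplitudes))
  if (any(!is.finite(angles)) || is.unsorted(angles, strictly = TRUE))
    stopf("`amplitudes` colnames must be strictly increasing angles (deg)")
  assert_scalar_num(noise_floor, "noise_floor", lower = 0, upper = 1)
  assert_scalar_num(trial_jitter, "trial_jitter", lower = 0)
  structure(
    list(amplitudes = amplitudes[knee_muscles, , drop = FALSE],
         angles = angles,
         noise_floor = noise_floor,
         trial_jitter = trial_jitter),
    class = "emg_profile")
}

#' Profile amplitude of each muscle at a knee angle
#'
#' Linearly interpolates the profile's amplitude table; angles outside the
#' tabulated range are clamped to the nearest tabulated angle.
#'
#' @param profile An [activation_profile()].
#' @param angle Knee angle in degrees.
#' @return Named numeric vector over the canonical muscles.
#' @export
profile_amplitude <- function(profile, angle) {
  stopifnot(inherits(profile, "emg_profile"))
  assert_scalar_num(angle, "angle")
  out <- vapply(knee_muscles, function(m) {
    stats::approx(profile$angles, profile$amplitudes[m, ], xout = angle,
                  rule = 2)$y
  }, numeric(1))
  out
}

#' Profile-derived natural activation vector
#'
#' The mean activation pattern the default profile prescribes at a knee
#' angle, normalized like the EMG pipeline output (max-normalization by
#' default).  Useful as a known "natural" synergy when planting reference
#' torques for the evolutionary search.
#'
#' @param angle Knee angle in degrees.
#' @param profile An [activation_profile()].
#' @param method Normalization method, see [normalize_activations()].
#' @return An `activation_vector`.
#' @export
natural_activation <- function(angle, profile = activation_profile(),
                               method = "max") {
  normalize_activations(profile_amplitude(profile, angle), method = method)
}
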