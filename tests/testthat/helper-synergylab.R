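## Shared fixtures and independent oracles for the test suite.  Heavy
## computations (full study-protocol sessions, GA recovery runs) are
## memoised so several property tests can share one computation.

.memo <- new.env(parent = emptyenv())

memoise1 <- function(key, expr) {
  if (!is.null(.memo[[key]])) return(.memo[[key]])
  .memo[[key]] <- expr
  .memo[[key]]
}

## Short-session protocol for fast unit tests: same band/sampling as the
## study protocol, but short rests and small jitter.
quick_protocol <- function(n_trials = 3, knee_angle = 60, ...) {
  emg_protocol(n_trials = n_trials, rest_duration = 4,
               knee_angle = knee_angle, ...)
}

quick_profile <- function(...) {
  activation_profile(trial_jitter = 0.1, ...)
}

## One full study-protocol session per seed, reduced to the small results
## the localization property tests need.
localization_run <- function(seed) {
  proto <- emg_protocol(knee_angle = 60)
  prof <- activation_profile()
  session <- generate_session(proto, prof, seed = seed)
  sgs <- lapply(seq_len(nrow(session$samples)), function(ch)
    compute_spectrogram(session$samples[ch, ], session$sampling_rate))
  trace <- summed_activity(sgs)
  events <- detect_activity_events(trace)
  segments <- localize_trials(events, proto$n_trials, seed = seed)
  centers <- session$ground_truth$trial_centers
  tt <- trace$frame_times
  in_trial <- rep(FALSE, length(tt))
  for (ck in centers) in_trial <- in_trial | abs(tt - ck) <= 2.0
  mid_rest <- rep(TRUE, length(tt))
  for (ck in centers) mid_rest <- mid_rest & abs(tt - ck) > 30
  list(centers = centers,
       origins = segments$origin,
       events = events,
       n_frames = length(tt),
       threshold = trace$snr_threshold,
       trial_values = trace$values[in_trial],
       rest_values = trace$values[mid_rest],
       window_s = sgs[[1]]$window_s)
}

localization_study <- function(seeds = 101:120) {
  memoise1(paste0("locstudy_", seeds[1], "_", length(seeds)),
           lapply(seeds, localization_run))
}

## The acceptance-scale single session (study defaults, seed 42).
acceptance_localization <- function() {
  memoise1("acc_loc42", localization_run(42))
}

## Independent static-torque oracle: recomputes sum(F * r) directly from
## the model parameter list, separately from the package's torque code.
oracle_extension_torque <- function(model, activations, theta) {
  total <- 0
  for (i in seq_along(knee_muscles)) {
    p <- model$muscles[[knee_muscles[i]]]
    cf <- as.numeric(p$moment_arm_poly_m)
    r <- 0
    for (j in seq_along(cf)) r <- r + cf[j] * theta^(j - 1)
    af <- as.numeric(p$fiberlen_affine)
    lt <- af[1] + (if (length(af) > 1) af[2] * theta else 0)
    f_l <- exp(-((lt - 1) / p$fl_width)^2)
    f_p <- if (lt > 1) (exp(p$kpe * (lt - 1) / p$e0_strain) - 1) /
      (exp(p$kpe) - 1) else 0
    total <- total + p$fmax_n * (activations[i] * f_l + f_p) * r
  }
  total
}

## GA parameter-recovery runs: plant the profile's natural activation at
## `angle`, measure its balancing torque, evolve against it over `seeds`.
ga_recovery <- function(angle, seeds) {
  memoise1(paste0("ga_", angle, "_", seeds[1], "_", length(seeds)), {
    model <- memoise1("model_default", knee_model())
    nat <- natural_activation(angle)
    ref <- balancing_torque(nat, angle, model)$balancing_torque
    runs <- lapply(seeds, function(s)
      evolve(evolution_task(angle, ref, model), ga_config(seed = s)))
    torques <- vapply(runs, function(r)
      balancing_torque(r$best, angle, model)$balancing_torque, numeric(1))
    list(reference = ref, runs = runs, torques = torques)
  })
}

default_model <- function() memoise1("model_default", knee_model())
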