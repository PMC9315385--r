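test_that("protocol and profile constructors enforce their invariants", {
  expect_s3_class(emg_protocol(), "emg_protocol")
  expect_error(emg_protocol(n_trials = 0), "n_trials")
  expect_error(emg_protocol(trial_duration = -1), "trial_duration")
  expect_error(emg_protocol(band = c(450, 20)), "band")
  expect_error(emg_protocol(band = c(20, 1200)), "band")
  expect_error(emg_protocol(muscles = c("RF", "VL")), "7 unique")
  amp <- activation_profile()$amplitudes
  amp[1, 1] <- 2
  expect_error(activation_profile(amp), "\\[0, 1\\]")
  bad <- activation_profile()$amplitudes
  rownames(bad)[1] <- "XX"
  expect_error(activation_profile(bad), "canonical")
})

test_that("default profile has the expected correlation-sign structure", {
  prof <- activation_profile()
  angles <- prof$angles
  for (m in c("RF", "VL", "VM")) {
    expect_true(all(diff(prof$amplitudes[m, ]) < 0),
                info = paste(m, "must decrease with angle"))
    expect_lt(cor(angles, prof$amplitudes[m, ]), 0)
  }
  for (m in c("Se", "TA"))
    expect_true(all(diff(prof$amplitudes[m, ]) >= 0),
                info = paste(m, "must weakly increase with angle"))
})

test_that("generated sessions follow the protocol schedule", {
  run <- acceptance_localization()
  proto <- emg_protocol(knee_angle = 60)
  expect_length(run$centers, proto$n_trials)
  ## nominal centre of trial i: i rests + (i-1) trials + half a trial
  nominal <- proto$rest_duration * seq_len(proto$n_trials) +
    proto$trial_duration * (seq_len(proto$n_trials) - 1) +
    proto$trial_duration / 2
  expect_true(all(abs(run$centers - nominal) <= 3 * 0.5))
  expect_true(all(diff(run$centers) > 0))
  spacing <- proto$trial_duration + proto$rest_duration
  expect_true(all(abs(diff(run$centers) - spacing) <= 6 * 0.5))
})

test_that("session dimensions and determinism contracts hold", {
  proto <- quick_protocol()
  prof <- quick_profile()
  s1 <- generate_session(proto, prof, seed = 7)
  s2 <- generate_session(proto, prof, seed = 7)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$ground_truth, s2$ground_truth)
  dur <- proto$n_trials * proto$trial_duration +
    (proto$n_trials + 1) * proto$rest_duration
  expect_equal(ncol(s1$samples), round(dur * proto$sampling_rate))
  expect_equal(rownames(s1$samples), knee_muscles)
  s3 <- generate_session(proto, prof, seed = 8)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("zero-activation sessions are indistinguishable from the noise floor", {
  proto <- quick_protocol()
  amp <- quick_profile()$amplitudes
  amp[] <- 0
  prof <- activation_profile(amp, noise_floor = 0.05, trial_jitter = 0.1)
  s <- generate_session(proto, prof, seed = 11)
  fs <- proto$sampling_rate
  tgrid <- (seq_len(ncol(s$samples)) - 1) / fs
  for (ck in s$ground_truth$trial_centers) {
    rms_trial <- sqrt(mean(s$samples[1, abs(tgrid - ck) <= 2]^2))
    expect_equal(rms_trial, 0.05, tolerance = 0.1)
  }
  rms_rest <- sqrt(mean(s$samples[1, tgrid < 3]^2))
  expect_equal(rms_rest, 0.05, tolerance = 0.1)
})

test_that("in-trial signal power is confined to the protocol band", {
  ## single 5-s burst at amplitude 1, negligible floor, averaged over seeds
  proto <- emg_protocol(n_trials = 1, rest_duration = 1, knee_angle = 0)
  amp <- activation_profile()$amplitudes
  amp[] <- 1
  prof <- activation_profile(amp, noise_floor = 1e-4, trial_jitter = 0)
  frac <- vapply(1:10, function(sd) {
    s <- generate_session(proto, prof, seed = sd)
    ck <- s$ground_truth$trial_centers[1]
    fs <- s$sampling_rate
    i <- round((ck - 2) * fs):round((ck + 2) * fs)
    x <- s$samples[3, i]
    spec <- abs(fft(x))^2
    freq <- (seq_along(spec) - 1) / length(spec) * fs
    fpos <- pmin(freq, fs - freq)
    sum(spec[fpos >= 20 & fpos <= 450]) / sum(spec)
  }, numeric(1))
  expect_gte(mean(frac), 0.95)
})

test_that("in-trial RMS grows monotonically with profile amplitude", {
  proto <- quick_protocol(n_trials = 1)
  rms_at <- function(a) {
    amp <- activation_profile()$amplitudes
    amp[] <- a
    prof <- activation_profile(amp, noise_floor = 0.05, trial_jitter = 0)
    s <- generate_session(proto, prof, seed = 21)
    ck <- s$ground_truth$trial_centers[1]
    tgrid <- (seq_len(ncol(s$samples)) - 1) / s$sampling_rate
    sqrt(mean(s$samples[, abs(tgrid - ck) <= 2]^2))
  }
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), rms_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("overlap-prone jitter and invalid inputs are rejected", {
  proto <- emg_protocol(n_trials = 3, rest_duration = 2)
  prof <- activation_profile(trial_jitter = 0.5)  # 3 sd = 1.5 s vs 2 s rest
  expect_error(generate_session(proto, prof, seed = 1), "overlap")
  expect_error(generate_session(quick_protocol(), quick_profile(),
                                seed = 1, trial_scale = c(1, -1, 1)),
               "nonnegative")
})
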