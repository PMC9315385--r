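test_that("trial spectra behave like plain FFT magnitudes", {
  proto <- quick_protocol(n_trials = 2)
  s <- generate_session(proto, quick_profile(), seed = 13)
  fs <- s$sampling_rate
  ## overwrite channel 1 with zeros and channel 2 with a 100 Hz tone
  s$samples[1, ] <- 0
  tgrid <- (seq_len(ncol(s$samples)) - 1) / fs
  s$samples[2, ] <- sin(2 * pi * 100 * tgrid)
  seg <- localize_trials(s$ground_truth$trial_centers, 2, seed = 1)
  sp <- trial_spectra(s, seg)
  expect_true(all(sp$v[, 1, ] == 0))
  peak <- sp$frequencies[which.max(sp$v[, 2, 1])]
  expect_lt(abs(peak - 100), 2 * diff(sp$frequencies[1:2]))
  ## Parseval: spectrum energy equals segment energy (time-domain oracle)
  i0 <- round(seg$onset[1] * fs) + 1
  i1 <- round(seg$offset[1] * fs)
  x <- s$samples[3, i0:i1]
  v <- sp$v[, 3, 1]
  n <- length(x)
  nb <- length(v)
  e_freq <- if (n %% 2 == 0)
    (v[1]^2 + v[nb]^2 + 2 * sum(v[2:(nb - 1)]^2)) / n
  else (v[1]^2 + 2 * sum(v[2:nb]^2)) / n
  expect_equal(e_freq, sum(x^2), tolerance = 1e-6)
})

test_that("segments beyond the recording bounds are rejected", {
  s <- generate_session(quick_protocol(n_trials = 1), quick_profile(),
                        seed = 2)
  seg <- data.frame(origin = 1e4, onset = 1e4 - 2.5, offset = 1e4 + 2.5,
                    cluster = 1)
  class(seg) <- c("trial_segments", "data.frame")
  expect_error(trial_spectra(s, seg), "bounds")
})

test_that("activation feature equals the weighted spectral sum", {
  expect_equal(activation_feature(list(frequency = c(50, 100, 150),
                                       amplitude = c(0, 0, 0)), 450), 0)
  expect_equal(activation_feature(list(frequency = 100, amplitude = 2),
                                  450), 200)
  set.seed(8)
  freq <- seq(20, 500, length.out = 50)
  amp <- runif(50)
  cutoff <- 330
  ## independent elementwise oracle
  oracle <- 0
  for (i in seq_along(freq))
    if (freq[i] >= 20 && freq[i] <= cutoff)
      oracle <- oracle + freq[i] * amp[i]
  expect_equal(activation_feature(list(frequency = freq, amplitude = amp),
                                  cutoff), oracle)
  ## linearity in the spectrum
  for (c_ in c(0, 0.5, 3)) {
    expect_equal(
      activation_feature(list(frequency = freq, amplitude = c_ * amp), cutoff),
      c_ * activation_feature(list(frequency = freq, amplitude = amp), cutoff))
  }
  expect_error(activation_feature(list(frequency = freq, amplitude = amp),
                                  10), "empty frequency range")
})

test_that("normalization scales the maximum to one and preserves ratios", {
  f <- c(2, 1, 0, 0, 0, 0, 0)
  a <- normalize_activations(f)
  expect_equal(as.numeric(a), c(1, 0.5, 0, 0, 0, 0, 0))
  set.seed(9)
  f2 <- runif(7, 0.1, 5)
  a2 <- normalize_activations(f2)
  expect_equal(max(a2), 1)
  expect_equal(as.numeric(a2[2] / a2[5]), f2[2] / f2[5], tolerance = 1e-12)
  ## idempotence
  a3 <- normalize_activations(as.numeric(a2))
  expect_equal(as.numeric(a3), as.numeric(a2))
  expect_error(normalize_activations(rep(0, 7)), "no muscle activity")
})

test_that("RF normalization clips values above one with a warning", {
  f <- c(RF = 1, VL = 2, VM = 0.5, Se = 0, BF = 0, MG = 0, TA = 0)
  expect_warning(a <- normalize_activations(f, method = "rf"), "clipped")
  expect_equal(as.numeric(a[["VL"]]), 1)
  expect_equal(as.numeric(a[["RF"]]), 1)
  expect_equal(as.numeric(a[["VM"]]), 0.5)
})

test_that("raising one muscle's amplitude raises its feature", {
  proto <- quick_protocol(n_trials = 2)
  amp_lo <- quick_profile()$amplitudes
  amp_hi <- amp_lo
  amp_hi["BF", ] <- pmin(1, amp_lo["BF", ] * 2)
  lo <- generate_session(proto, activation_profile(amp_lo, trial_jitter = 0.1),
                         seed = 17)
  hi <- generate_session(proto, activation_profile(amp_hi, trial_jitter = 0.1),
                         seed = 17)
  seg <- localize_trials(lo$ground_truth$trial_centers, 2, seed = 1)
  f_of <- function(sess) {
    sp <- trial_spectra(sess, seg)
    activation_feature(list(frequency = sp$frequencies,
                            amplitude = sp$v[, "BF", 1]), 450)
  }
  expect_gt(f_of(hi), f_of(lo))
})
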