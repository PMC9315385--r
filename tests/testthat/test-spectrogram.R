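test_that("a pure tone concentrates magnitude in its frequency bin", {
  fs <- 1900
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 100 * t)
  sg <- compute_spectrogram(x, fs)
  peak_bin <- apply(sg$magnitudes, 2, which.max)
  expect_true(all(abs(sg$frequencies[peak_bin] - 100) <=
                    diff(sg$frequencies[1:2])))
})

test_that("an all-zero signal yields an all-zero spectrogram", {
  sg <- compute_spectrogram(numeric(2000), 1900)
  expect_true(all(sg$magnitudes == 0))
  expect_equal(sg$frequencies[1], 0)
  expect_lte(max(sg$frequencies), 950)
})

test_that("frame energy satisfies Parseval against a time-domain oracle", {
  set.seed(99)
  fs <- 1000
  x <- rnorm(1000)
  sg <- compute_spectrogram(x, fs, window_s = 0.1, hop_s = 0.05)
  nwin <- round(0.1 * fs)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1)))
  starts <- seq(1, length(x) - nwin + 1, by = round(0.05 * fs))
  for (k in seq_along(starts)) {
    xi <- x[starts[k]:(starts[k] + nwin - 1)] * w
    e_time <- sum(xi^2)
    mag <- sg$magnitudes[, k]
    ## reconstruct full-spectrum energy from the one-sided magnitudes
    nb <- length(mag)
    if (nwin %% 2 == 0) {
      e_freq <- (mag[1]^2 + mag[nb]^2 + 2 * sum(mag[2:(nb - 1)]^2)) / nwin
    } else {
      e_freq <- (mag[1]^2 + 2 * sum(mag[2:nb]^2)) / nwin
    }
    expect_equal(e_freq, e_time, tolerance = 1e-6)
  }
})

test_that("spectrogram input validation rejects degenerate signals", {
  expect_error(compute_spectrogram(numeric(0), 1900), "empty")
  expect_error(compute_spectrogram(c(1, NA, 3), 1900), "finite")
  expect_error(compute_spectrogram(rnorm(1000), 1900, window_s = 0.1,
                                   hop_s = 0.2), "hop_s")
  expect_error(compute_spectrogram(rnorm(10), 1900), "shorter")
})

make_sg <- function(mag, freqs = seq_len(nrow(mag)) - 1,
                    times = seq_len(ncol(mag)) - 1) {
  structure(list(magnitudes = mag, frequencies = freqs, frame_times = times,
                 window_s = 1, hop_s = 1, window = "hann",
                 sampling_rate = 2 * max(freqs)),
            class = "emg_spectrogram")
}

test_that("summed activity adds channels then frequencies", {
  sg <- make_sg(matrix(c(1, 2, 3), ncol = 1))
  tr <- summed_activity(list(sg))
  expect_equal(tr$values, 6)
  tr2 <- summed_activity(list(sg, sg))
  expect_equal(tr2$values, 12)
  sg_big <- make_sg(matrix(runif(50), 5, 10))
  expect_equal(summed_activity(list(sg_big, sg_big))$values,
               2 * summed_activity(list(sg_big))$values)
})

test_that("summed activity requires matching grids", {
  a <- make_sg(matrix(1, 2, 3))
  b <- make_sg(matrix(1, 2, 3), freqs = c(0, 2))
  expect_error(summed_activity(list(a, b)), "grids")
})

test_that("event detection is strict at the threshold", {
  tr <- structure(list(values = c(1, 2, 3, 2, 1), frame_times = 0:4,
                       snr_threshold = 2, k_sigma = 3),
                  class = "activity_trace")
  expect_equal(detect_activity_events(tr), 2)  # only the strict exceedance
  tr$snr_threshold <- 10
  expect_equal(detect_activity_events(tr), numeric(0))
})

test_that("localization reproduces singleton clusters exactly", {
  seg <- localize_trials(c(10, 20, 30), 3, seed = 1)
  expect_equal(seg$origin, c(10, 20, 30))
  expect_equal(seg$onset, c(7.5, 17.5, 27.5))
  expect_equal(seg$offset, c(12.5, 22.5, 32.5))
})

test_that("cluster origins are medians, matching brute-force partitioning", {
  events <- c(9.9, 10.0, 10.1, 200.0)
  ## oracle: best contiguous 2-partition of sorted 1-D events by within-SS
  best <- NULL
  for (cut in 1:3) {
    g1 <- events[1:cut]; g2 <- events[(cut + 1):4]
    ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    if (is.null(best) || ss < best$ss)
      best <- list(ss = ss, origins = c(median(g1), median(g2)))
  }
  expect_equal(best$origins, c(10, 200))  # frozen oracle expectation
  seg <- localize_trials(events, 2, seed = 3)
  expect_equal(seg$origin, best$origins)
})

test_that("localization rejects insufficient events", {
  expect_error(localize_trials(c(1, 2), 3), "insufficient activity events")
  expect_error(localize_trials(rep(5, 10), 3), "insufficient")
})

test_that("trial localization recovers ground truth on study-scale sessions", {
  runs <- localization_study()
  expect_length(runs, 20)
  for (run in runs) {
    ## criterion-scale recovery: right count, origins near ground truth
    expect_length(run$origins, 6)
    expect_true(all(abs(run$origins - run$centers) <= 0.25))
    ## the trace separates trials from rest: all in-trial frames exceed the
    ## threshold; rest frames stay below it up to the 3-sigma false-positive
    ## rate of a Gaussian-like trace
    expect_true(all(run$trial_values > run$threshold))
    expect_lt(mean(run$rest_values > run$threshold), 0.005)
    ## events lie within a trial window extended by one window length,
    ## except for sparse threshold exceedances at the 3-sigma false rate
    near <- vapply(run$events, function(e)
      any(abs(e - run$centers) <= 2.5 + run$window_s), logical(1))
    expect_lt(sum(!near) / run$n_frames, 0.005)
    expect_gt(mean(near), 0.75)
  }
})
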