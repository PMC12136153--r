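test_that("baseline statistics cover exactly the 500 ms before onset", {
  tr <- make_trace(rep(-52.7, 10000))
  b <- baseline_stats(tr)
  expect_equal(b$mean, -52.7)
  expect_equal(b$sd, 0)
  # samples after onset never contaminate the window
  v <- rep(0, 10000); v[5001:10000] <- 100
  b2 <- baseline_stats(make_trace(v))
  expect_equal(b2$mean, 0)
  expect_equal(b2$sd, 0)
  expect_error(baseline_stats(make_trace(rep(0, 10000), onset = 300)),
               "baseline")
})

test_that("sinusoidal baseline has RMS amplitude a/sqrt(2)", {
  a <- 2
  t <- seq(0, 999.9, by = 0.1)
  v <- -50 + a * sin(2 * pi * 10 * t / 1000)  # 10 Hz, whole cycles in 500 ms
  b <- baseline_stats(make_trace(v))
  expect_equal(b$sd, a / sqrt(2), tolerance = 0.01)
})

test_that("latency finds a clean step and ignores pure noise", {
  step <- make_shaped_trace(function(t) ifelse(t >= 15, 20, 0))
  lat <- onset_latency(step)
  expect_equal(lat$latency_ms, 15, tolerance = 0.11)
  expect_identical(lat$polarity, "depolarizing")
  set.seed(4)
  noise <- make_trace(rnorm(10000, -52.7, 1))
  expect_true(is.na(onset_latency(noise)$latency_ms))
})

test_that("latency is invariant under voltage translation", {
  set.seed(5)
  cell <- sim_cell_spec("UV", lambda_max = 370, noise_sd = 1)
  tr <- simulate_trace(cell, 370)
  l1 <- onset_latency(tr)$latency_ms
  tr$voltage_mV <- tr$voltage_mV + 7.3
  expect_equal(onset_latency(tr)$latency_ms, l1)
})

test_that("latency at lambda_max matches the generative latency within one sample", {
  cell <- sim_cell_spec("UV", lambda_max = 365, noise_sd = 0)
  tr <- simulate_trace(cell, 365)
  expect_equal(onset_latency(tr)$latency_ms, cell$response_latency,
               tolerance = 0.11)
})

test_that("half-max duration is exact for rectangles and triangles", {
  rect <- make_shaped_trace(function(t) ifelse(t >= 10 & t < 90, 20, 0))
  expect_equal(halfmax_duration(rect), 80, tolerance = 0.05)
  tri <- make_shaped_trace(function(t)
    pmax(0, 20 * (1 - abs(t - 40) / 40)))  # base 80 ms
  expect_equal(halfmax_duration(tri), 40, tolerance = 0.15)
  flat <- make_trace(rep(-52.7, 10000))
  expect_true(is.na(halfmax_duration(flat)))
})

test_that("the adapting LED shortens the half-max duration", {
  cell <- sim_cell_spec("green", noise_sd = 0)
  off <- simulate_trace(cell, 550, led_on = FALSE)
  on <- simulate_trace(cell, 550, led_on = TRUE)
  expect_lt(halfmax_duration(on), halfmax_duration(off))
})

test_that("adaptation deltas reproduce the ratio arithmetic and QC rule", {
  before <- feature_row(30, baseline_mean = -52.7)
  during <- feature_row(30 * 0.209, baseline_mean = -58.3)
  after <- feature_row(30)
  ad <- adaptation_deltas(before, during, after)
  expect_equal(ad$amplitude_ratio, 0.209)
  expect_equal(ad$delta_resting_mV, -5.6)
  expect_equal(ad$recovery_fraction, 1)
  expect_true(ad$qc_pass)
  bad <- adaptation_deltas(before, during, feature_row(30 * 0.7))
  expect_equal(bad$recovery_fraction, 0.7)
  expect_false(bad$qc_pass)
  expect_error(adaptation_deltas(before, during,
                                 feature_row(30, wavelength = 530)),
               "same wavelength")
})

test_that("cell QC applies the 30 mV and recovery criteria with reasons", {
  expect_true(qc_cell(35, 0.95)$pass)
  f <- qc_cell(25, 0.95)
  expect_false(f$pass)
  expect_identical(f$reasons, "amplitude")
  expect_identical(qc_cell(35, 0.7)$reasons, "recovery")
  expect_identical(qc_cell(35, 0.95, baseline_drift_mV_s = 20)$reasons,
                   "drift")
})

test_that("repeat averaging reduces noise before feature extraction", {
  set.seed(6)
  cell <- sim_cell_spec("UV", lambda_max = 370, noise_sd = 2)
  reps <- lapply(1:4, function(r) simulate_trace(cell, 370))
  f <- trace_features(reps)
  expect_equal(f$n_repeats, 4)
  expect_lt(f$baseline_sd_mV, 2 / sqrt(4) * 1.3)
  expect_identical(f$polarity, "depolarizing")
})
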