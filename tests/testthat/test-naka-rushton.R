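nr_curve <- function(lI, v_max = 40, n = 1, lK = 14.5) {
  v_max / (1 + 10^(n * (lK - lI)))
}

test_that("noiseless Naka-Rushton parameters are recovered exactly", {
  lI <- seq(11.18, 15.18, length.out = 9)
  fit <- fit_naka_rushton(lI, nr_curve(lI))
  expect_true(fit$converged)
  expect_equal(fit$v_max, 40, tolerance = 1e-6)
  expect_equal(fit$log10_K, 14.5, tolerance = 1e-6)
  expect_equal(fit$n, 1, tolerance = 1e-6)
  # V(K) = v_max / 2 by definition
  expect_equal(predict(fit, fit$log10_K), fit$v_max / 2,
               tolerance = 1e-9)
})

test_that("noisy fits recover v_max to a few percent", {
  set.seed(11)
  lI <- seq(11.18, 15.18, length.out = 9)
  err <- replicate(100, {
    fit <- fit_naka_rushton(lI, nr_curve(lI, lK = 13.8) + rnorm(9, 0, 1))
    if (fit$converged) abs(fit$v_max - 40) / 40 else NA
  })
  expect_lt(median(err, na.rm = TRUE), 0.05)
})

test_that("degenerate V-log(I) series are flagged, not fitted", {
  lI <- seq(11, 15, length.out = 9)
  down <- fit_naka_rushton(lI, rev(nr_curve(lI)))
  expect_false(down$converged)
  expect_identical(down$flags, "non_monotone")
  short <- fit_naka_rushton(lI[1:4], nr_curve(lI[1:4]))
  expect_identical(short$flags, "too_few_levels")
  weak <- fit_naka_rushton(lI, nr_curve(lI, v_max = 2), noise_sd = 1)
  expect_identical(weak$flags, "low_snr")
})

test_that("equivalent intensity inverts the fitted curve and clamps saturation", {
  lI <- seq(11.18, 15.18, length.out = 9)
  fit <- fit_naka_rushton(lI, nr_curve(lI))
  expect_equal(as.numeric(log10(equivalent_intensity(fit, 20))), 14.5,
               tolerance = 1e-6)
  over <- equivalent_intensity(fit, 45)
  expect_true(attr(over, "clamped"))
  expect_true(is.finite(over))
})

test_that("half-saturating responses give a flat unit sensitivity", {
  lI <- seq(11.18, 15.18, length.out = 9)
  fit <- fit_naka_rushton(lI, nr_curve(lI))
  resp <- data.frame(wavelength_nm = seq(310, 630, 10),
                     amplitude_mV = rep(20, 33))
  s <- responses_to_sensitivity(resp, fit)
  expect_true(all(abs(s$value - 1) < 1e-9))
})

test_that("sensitivity ratios obey the n = 1 algebraic identity", {
  lI <- seq(11.18, 15.18, length.out = 9)
  fit <- fit_naka_rushton(lI, nr_curve(lI))
  v1 <- 31.2; v2 <- 9.7
  s <- responses_to_sensitivity(
    data.frame(wavelength_nm = c(370, 530),
               amplitude_mV = c(v1, v2)), fit)
  expect_equal(s$value[s$wavelength == 530] / s$value[s$wavelength == 370],
               (v2 / (fit$v_max - v2)) / (v1 / (fit$v_max - v1)),
               tolerance = 1e-9)
})

test_that("forward-simulated responses invert back to the template", {
  # zero-noise forward model at the amplitude level, then NR inversion
  lm <- 390
  wl <- seq(310, 630, 10)
  tplv <- rhodopsin_template(lm, grid = wl)$value
  I0 <- 1.5e15
  v_of <- function(q) 40 * q / (q + 10^13.8)
  lI <- seq(11.18, log10(I0), length.out = 9)
  fit <- fit_naka_rushton(lI, v_of(10^lI))
  s <- responses_to_sensitivity(
    data.frame(wavelength_nm = wl, amplitude_mV = v_of(tplv * I0)),
    fit, isoquantal_intensity = I0)
  expect_equal(s$value, tplv / max(tplv), tolerance = 1e-3)
})

test_that("hyperpolarizing responses map to zero sensitivity but stay flagged", {
  lI <- seq(11.18, 15.18, length.out = 9)
  fit <- fit_naka_rushton(lI, nr_curve(lI))
  s <- responses_to_sensitivity(
    data.frame(wavelength_nm = c(370, 530, 550),
               amplitude_mV = c(35, -6, -4)), fit)
  expect_equal(s$value[2:3], c(0, 0))
  expect_identical(attr(s, "hyperpolarizing"), c(FALSE, TRUE, TRUE))
})
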