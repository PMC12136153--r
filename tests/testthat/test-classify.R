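fit_template_sens <- function(lm, wl = seq(310, 630, 10)) {
  s <- rhodopsin_template(lm, grid = wl)
  s$kind <- "sensitivity"
  list(fit = fit_lambda_max(s), sens = s)
}

test_that("lambda_max ranges partition into the five spectral classes", {
  expect_identical(do.call(classify_photoreceptor,
                           fit_template_sens(360)), "UV")
  expect_identical(do.call(classify_photoreceptor,
                           fit_template_sens(470)), "blue")
  expect_identical(do.call(classify_photoreceptor,
                           fit_template_sens(550)), "green")
  expect_identical(do.call(classify_photoreceptor,
                           fit_template_sens(600)), "redLW")
})

test_that("class boundaries partition lambda_max space without overlap", {
  for (lm in seq(340, 620, by = 7)) {
    cls <- do.call(classify_photoreceptor, fit_template_sens(lm))
    expected <- if (lm < 420) "UV" else if (lm < 500) "blue"
      else if (lm < 580) "green" else "redLW"
    expect_identical(cls, expected)
  }
})

test_that("opsin-coexpression mixtures classify as broadband by bandwidth", {
  wl <- seq(310, 630, 10)
  mix <- 0.55 * rhodopsin_template(460, grid = wl)$value +
    0.55 * rhodopsin_template(570, grid = wl)$value
  s <- spectrum(wl, pmin(mix, 1), "sensitivity")
  fit <- fit_lambda_max(s)
  expect_identical(classify_photoreceptor(fit, s), "broadband")
})

test_that("inhibition scoring follows the sign-and-magnitude rule", {
  lmax_row <- feature_row(35)
  # hyperpolarizing, clearly beyond noise: -0.2 normalized = -7 mV
  inh <- classify_inhibition(feature_row(-7, wavelength = 530), lmax_row)
  expect_true(inh$inhibited)
  expect_equal(inh$inhibition_amplitude, -0.2)
  # depolarizing probe response: never inhibited
  pos <- classify_inhibition(feature_row(3.5, wavelength = 530), lmax_row)
  expect_false(pos$inhibited)
  # hyperpolarizing but within noise (threshold 5 * 0.4 = 2 mV)
  weak <- classify_inhibition(feature_row(-1.5, wavelength = 530),
                              lmax_row)
  expect_false(weak$inhibited)
  # missing probe wavelength: undefined, excluded downstream
  none <- classify_inhibition(NULL, lmax_row)
  expect_true(is.na(none$inhibited))
})

test_that("probe wavelengths are 530 nm for UV and 590 nm for blue", {
  expect_equal(probe_wavelength("UV"), 530)
  expect_equal(probe_wavelength("blue"), 590)
  expect_error(probe_wavelength("green"), "UV and blue")
})

test_that("zero-noise recordings classify class and inhibition exactly", {
  for (inh in c(TRUE, FALSE)) {
    cell <- sim_cell_spec("UV", lambda_max = 368, inhibited = inh,
                          noise_sd = 0)
    rec <- simulate_recording(cell, cell_id = "c", individual_id = "i",
                              group = "g")
    row <- analyze_recording(rec)
    expect_identical(row$cell_class, "UV")
    expect_identical(row$inhibited, inh)
    expect_lt(abs(row$lambda_max_nm - 368), 2)
  }
})

test_that("inhibited cells show the delayed probe latency, non-inhibited do not", {
  cell <- sim_cell_spec("UV", lambda_max = 368, inhibited = TRUE,
                        noise_sd = 0)
  rec <- simulate_recording(cell, cell_id = "c", individual_id = "i",
                            group = "g")
  row <- analyze_recording(rec)
  expect_gt(row$probe_latency_ms, row$lmax_latency_ms)
  cell2 <- sim_cell_spec("UV", lambda_max = 368, inhibited = FALSE,
                         noise_sd = 0)
  rec2 <- simulate_recording(cell2, cell_id = "c", individual_id = "i",
                             group = "g")
  row2 <- analyze_recording(rec2)
  expect_false(row2$inhibited)
})
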