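test_that("saturating flash plateaus at resting + max_depol", {
  cell <- sim_cell_spec("UV", lambda_max = 360, noise_sd = 0)
  tr <- simulate_trace(cell, 360, intensity = 1e19)
  expect_equal(max(tr$voltage_mV), cell$resting_potential + cell$max_depol,
               tolerance = 1e-3)
  expect_equal(tr$voltage_mV[1], cell$resting_potential)
})

test_that("inhibited cell's long-wavelength response is a delayed hyperpolarization", {
  cell <- sim_cell_spec("UV", lambda_max = 360, inhibited = TRUE,
                        noise_sd = 0)
  probe <- simulate_trace(cell, 550)
  lat <- onset_latency(probe)
  expect_identical(lat$polarity, "hyperpolarizing")
  peak <- simulate_trace(cell, 360)
  lat0 <- onset_latency(peak)
  expect_identical(lat0$polarity, "depolarizing")
  expect_equal(lat$latency_ms - lat0$latency_ms, cell$inhibition_delay,
               tolerance = 0.11)
})

test_that("traces are seed-deterministic", {
  cell <- sim_cell_spec("UV", noise_sd = 1.5)
  set.seed(123); a <- simulate_trace(cell, 370)
  set.seed(123); b <- simulate_trace(cell, 370)
  set.seed(124); c <- simulate_trace(cell, 370)
  expect_identical(a$voltage_mV, b$voltage_mV)
  expect_false(identical(a$voltage_mV, c$voltage_mV))
})

test_that("unphysical stimuli and specs are rejected", {
  cell <- sim_cell_spec("UV")
  expect_error(simulate_trace(cell, 370, intensity = -1), "non-negative")
  expect_error(simulate_trace(cell, 370, duration = 700, onset = 500),
               "before the trace")
  expect_error(sim_cell_spec("UV", noise_sd = -1), "noise_sd")
  expect_warning(sim_cell_spec("UV", max_depol = 25), "quality control")
})

test_that("experiment truth tables respect the requested design", {
  groups <- data.frame(group = c("a", "b"), n_individuals = c(3L, 2L),
                       n_cells = c(9L, 6L), p_inhibition = c(0, 1))
  spec <- sim_experiment_spec(groups = groups, seed = 5)
  set.seed(spec$seed)
  truth <- specsens:::draw_truth_table(spec)
  expect_equal(as.vector(table(truth$group)[c("a", "b")]), c(9L, 6L))
  expect_equal(length(unique(truth$individual_id[truth$group == "a"])), 3L)
  expect_false(any(truth$inhibited[truth$group == "a"]))
  expect_true(all(truth$inhibited[truth$group == "b"]))
  expect_true(all(truth$lambda_max >= 345 & truth$lambda_max <= 404))
})

test_that("inhibition draws are binomial at the requested prevalence", {
  groups <- data.frame(group = "g", n_individuals = 10L, n_cells = 500L,
                       p_inhibition = 0.7)
  spec <- sim_experiment_spec(groups = groups, seed = 21)
  set.seed(spec$seed)
  truth <- specsens:::draw_truth_table(spec)
  frac <- mean(truth$inhibited)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 500))
})

test_that("simulated recordings are reproducible and small ones complete", {
  cell <- sim_cell_spec("UV", lambda_max = 370, noise_sd = 1)
  set.seed(9)
  rec <- simulate_recording(cell, wavelengths = c(350, 370, 530),
                            repeats = 2, vlogi_levels = 5)
  expect_length(rec$spectral, 6)
  expect_length(rec$vlogi, 5)
  expect_equal(rec$peak_stimulus_nm, 370)
})

test_that("wing reflectance matches the white/yellow phenotypes", {
  g <- seq(300, 700, 1)
  yel <- simulate_wing_reflectance("yellow", g)
  wht <- simulate_wing_reflectance("white", g)
  at <- function(s, w) s$value[s$wavelength == w]
  expect_lt(at(yel, 350), 0.01)
  expect_gte(at(wht, 350), 0.5 * max(wht$value))
  expect_lt(abs(at(yel, 600) / at(wht, 600) - 1), 0.1)
  expect_error(simulate_wing_reflectance("green", g), "arg")
})

test_that("sensitivity-level generator reduces to the template at zero noise", {
  s <- simulate_sensitivity(372, noise_sd = 0)
  tpl <- rhodopsin_template(372, grid = s$wavelength)
  expect_equal(s$value, tpl$value, tolerance = 1e-12)
})

test_that("LED blocks reproduce the configured adaptation directions", {
  # green cell: response collapses to ~21%, resting potential rises
  green <- sim_cell_spec("green", noise_sd = 0)
  recg <- simulate_recording(green, wavelengths = c(530, 550, 570),
                             repeats = 2, vlogi_levels = 5,
                             led_protocol = TRUE)
  ad <- adaptation_deltas(trace_features(recg$led$before),
                          trace_features(recg$led$during),
                          trace_features(recg$led$after))
  expect_equal(ad$amplitude_ratio, 0.209, tolerance = 0.01)
  expect_equal(ad$delta_resting_mV, 5.6, tolerance = 0.01)
  expect_true(ad$qc_pass)
  # inhibited UV cell: resting potential drops under the LED
  uvi <- sim_cell_spec("UV", lambda_max = 370, inhibited = TRUE,
                       noise_sd = 0)
  recu <- simulate_recording(uvi, wavelengths = c(350, 370, 530),
                             repeats = 2, vlogi_levels = 5,
                             led_protocol = TRUE)
  adu <- adaptation_deltas(trace_features(recu$led$before),
                           trace_features(recu$led$during),
                           trace_features(recu$led$after))
  expect_equal(adu$delta_resting_mV, -5.6, tolerance = 0.01)
  expect_lt(adu$amplitude_ratio, 1)
  # a poorly recovering cell fails QC through the pipeline
  bad <- sim_cell_spec("UV", lambda_max = 370, noise_sd = 0,
                       led_recovery = 0.7)
  recb <- simulate_recording(bad, wavelengths = c(350, 370, 530),
                             repeats = 2, vlogi_levels = 5,
                             led_protocol = TRUE)
  row <- analyze_recording(recb)
  expect_false(row$qc_pass)
  expect_match(row$qc_reasons, "recovery")
})
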