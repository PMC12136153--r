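#' Specification of one simulated photoreceptor
#'
#' Bundles the ground-truth parameters from which synthetic traces are
#' generated. Defaults mirror the recording conditions the analysis assumes:
#' resting potential -52.7 mV, saturating depolarizations of at least 30 mV,
#' and (for inhibited cells) a hyperpolarizing component whose onset lags
#' the excitatory latency by 5.4 ms, the signature of monosynaptic
#' color-opponent input from long-wavelength cells.
#'
#' Response kinetics are a difference of exponentials (rise tau 2 ms, decay
#' tau 80 ms): a fast initial depolarization followed by a slow decay, so
#' half-maximum durations fall in the tens-of-milliseconds range. The
#' inhibitory drive is the quantum catch of a green (550 nm) template, so
#' hyperpolarization appears at long wavelengths only.
#'
#' @param cell_class `"UV"`, `"blue"`, `"green"`, `"redLW"` or
#'   `"broadband"`.
#' @param lambda_max True peak sensitivity in nm (class default if `NULL`:
#'   UV 375, blue 470, green 550, redLW 600, broadband 500).
#' @param inhibited Does the cell receive long-wavelength inhibition?
#' @param inhibition_delay Delay of the inhibitory onset after the
#'   excitatory latency, ms (default 5.4).
#' @param inhibition_gain Inhibitory amplitude as a fraction of `max_depol`
#'   at full drive (default 0.25).
#' @param inhibition_band_min Shortest wavelength at which the inhibitory
#'   input acts, nm (default 500): opponent hyperpolarization appears in
#'   the long-wavelength band only, leaving the cell's own short-wavelength
#'   tuning uncontaminated.
#' @param resting_potential Dark resting potential, mV (default -52.7).
#' @param max_depol Saturating depolarization amplitude, mV (>= 30;
#'   default 40).
#' @param noise_sd Gaussian sample noise SD, mV (default 1.5).
#' @param naka_n Naka-Rushton exponent (default 1).
#' @param naka_log10K log10 half-saturation intensity in photons/cm^2/s
#'   (default 13.8, ~1.4 log units below the standard stimulus).
#' @param response_latency Excitatory transduction latency, ms (default 20).
#' @param rise_ms,decay_ms Kinetic time constants, ms.
#' @param led_amp_ratio Multiplicative attenuation of the excitatory
#'   amplitude while the adapting LED is on. Class/inhibition defaults:
#'   green cells 0.209 (responses reduced to ~21% of baseline), inhibited
#'   UV/blue 0.75, non-inhibited UV/blue 0.55 (the LED decrease is larger
#'   for cells without inhibition).
#' @param led_delta_rest Additive resting-potential shift while the LED is
#'   on, mV. Defaults: green +5.6, inhibited UV/blue -5.6 (tonic inhibition
#'   from persistently activated LW cells), non-inhibited UV/blue -1.4.
#' @param led_decay_factor Multiplies `decay_ms` while the LED is on
#'   (default 0.6; light adaptation speeds the response, shortening
#'   half-max durations).
#' @param led_recovery Fraction of the pre-LED response amplitude recovered
#'   after the LED is switched off (default 1; lower it to simulate cells
#'   failing the 80% recovery criterion).
#' @return An object of class `"sim_cell_spec"`.
#' @export
sim_cell_spec <- function(cell_class = c("UV", "blue", "green", "redLW",
                                         "broadband"),
                          lambda_max = NULL, inhibited = FALSE,
                          inhibition_delay = 5.4, inhibition_gain = 0.25,
                          inhibition_band_min = 500,
                          resting_potential = -52.7, max_depol = 40,
                          noise_sd = 1.5, naka_n = 1, naka_log10K = 13.8,
                          response_latency = 20, rise_ms = 2, decay_ms = 80,
                          led_amp_ratio = NULL, led_delta_rest = NULL,
                          led_decay_factor = 0.6, led_recovery = 1) {
  cell_class <- match.arg(cell_class)
  if (is.null(lambda_max))
    lambda_max <- c(UV = 375, blue = 470, green = 550, redLW = 600,
                    broadband = 500)[[cell_class]]
  if (max_depol < 30)
    warning("max_depol < 30 mV: this cell will fail quality control")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (inhibition_gain < 0 || inhibition_gain > 1)
    stop("inhibition_gain must be in [0, 1]")
  if (is.null(led_amp_ratio))
    led_amp_ratio <- if (cell_class == "green") 0.209
      else if (inhibited) 0.75 else 0.55
  if (is.null(led_delta_rest))
    led_delta_rest <- if (cell_class == "green") 5.6
      else if (inhibited) -5.6 else -1.4
  structure(list(cell_class = cell_class, lambda_max = lambda_max,
                 inhibited = inhibited, inhibition_delay = inhibition_delay,
                 inhibition_gain = inhibition_gain,
                 inhibition_band_min = inhibition_band_min,
                 resting_potential = resting_potential,
                 max_depol = max_depol, noise_sd = noise_sd,
                 naka_n = naka_n, naka_log10K = naka_log10K,
                 response_latency = response_latency,
                 rise_ms = rise_ms, decay_ms = decay_ms,
                 led_amp_ratio = led_amp_ratio,
                 led_delta_rest = led_delta_rest,
                 led_decay_factor = led_decay_factor,
                 led_recovery = led_recovery),
            class = "sim_cell_spec")
}

#' @export
print.sim_cell_spec <- function(x, ...) {
  cat(sprintf("<sim_cell_spec: %s, lambda_max %g nm, %s>\n", x$cell_class,
              x$lambda_max,
              if (x$inhibited) "LW-inhibited" else "no inhibition"))
  invisible(x)
}

# Naka-Rushton response fraction for effective drive q (photons/cm^2/s)
naka_rushton_frac <- function(q, n, log10K) {
  K <- 10^log10K
  ifelse(q <= 0, 0, q^n / (q^n + K^n))
}

# Difference-of-exponentials kernel, zero for t < 0, peak value 1
response_kernel <- function(t, rise, decay) {
  tp <- log(decay / rise) * rise * decay / (decay - rise)
  gmax <- exp(-tp / decay) - exp(-tp / rise)
  out <- numeric(length(t))
  p <- t > 0
  out[p] <- (exp(-t[p] / decay) - exp(-t[p] / rise)) / gmax
  out
}

# Deterministic (noise-free) response component amplitudes for a stimulus
sim_response_amplitudes <- function(cell, wavelength, intensity, led_on) {
  s_ex <- template_value(wavelength, cell$lambda_max)
  a_ex <- cell$max_depol *
    naka_rushton_frac(s_ex * intensity, cell$naka_n, cell$naka_log10K)
  a_inh <- 0
  if (isTRUE(cell$inhibited) && wavelength >= cell$inhibition_band_min) {
    s_inh <- template_value(wavelength, 550)
    a_inh <- cell$inhibition_gain * cell$max_depol *
      naka_rushton_frac(s_inh * intensity, cell$naka_n, cell$naka_log10K)
  }
  if (led_on) {
    a_ex <- a_ex * cell$led_amp_ratio
    a_inh <- a_inh * 0.209  # LW drive itself adapted to ~21% by the LED
  }
  list(excitatory = a_ex, inhibitory = a_inh)
}

#' Simulate one stimulus presentation
#'
#' Forward model of a single trace: Gaussian noise around the resting
#' potential, an excitatory depolarization whose amplitude follows the
#' Naka-Rushton function of the template-weighted quantum catch, and, for
#' inhibited cells, a hyperpolarizing component driven by a 550 nm template
#' catch whose onset is delayed by `inhibition_delay`. With the adapting
#' LED on, the resting potential shifts by `led_delta_rest`, amplitudes are
#' attenuated by `led_amp_ratio`, and the decay accelerates.
#'
#' @param cell A [sim_cell_spec()].
#' @param wavelength Stimulus wavelength, nm.
#' @param intensity Photon flux, photons/cm^2/s (default 1.5e15, the
#'   standard isoquantal stimulus).
#' @param led_on Adapting 534 nm LED state.
#' @param duration Trace length, ms (default 1000).
#' @param onset Stimulus onset, ms from trace start (default 500, leaving
#'   the full 500 ms baseline window).
#' @param flash_ms Flash duration, ms (default 300; shutter metadata only,
#'   the kinetic kernel is flash-evoked and transient).
#' @param sample_rate Samples per second (default 10000).
#' @param repeat_index Repeat number stored in the trace metadata.
#' @return An object of class `"pr_trace"`: list with `time_ms`,
#'   `voltage_mV`, `onset_ms` and stimulus metadata.
#' @examples
#' cell <- sim_cell_spec("UV", lambda_max = 360, noise_sd = 0)
#' tr <- simulate_trace(cell, 360)
#' range(tr$voltage_mV)
#' @export
simulate_trace <- function(cell, wavelength, intensity = 1.5e15,
                           led_on = FALSE, duration = 1000, onset = 500,
                           flash_ms = 300, sample_rate = 10000,
                           repeat_index = 1L) {
  stopifnot(inherits(cell, "sim_cell_spec"))
  if (intensity < 0) stop("intensity must be non-negative")
  if (onset + flash_ms >= duration)
    stop("onset + flash window must end before the trace does")
  dt <- 1000 / sample_rate
  time_ms <- seq(0, duration - dt, by = dt)
  amp <- sim_response_amplitudes(cell, wavelength, intensity, led_on)
  decay <- cell$decay_ms * if (led_on) cell$led_decay_factor else 1
  t_ex <- time_ms - onset - cell$response_latency
  v <- amp$excitatory * response_kernel(t_ex, cell$rise_ms, decay)
  if (amp$inhibitory > 0) {
    t_inh <- t_ex - cell$inhibition_delay
    v <- v - amp$inhibitory * response_kernel(t_inh, cell$rise_ms, decay)
  }
  base <- cell$resting_potential + if (led_on) cell$led_delta_rest else 0
  v <- base + v
  if (cell$noise_sd > 0)
    v <- v + stats::rnorm(length(v), 0, cell$noise_sd)
  structure(list(time_ms = time_ms, voltage_mV = v, onset_ms = onset,
                 wavelength_nm = wavelength, intensity = intensity,
                 led_on = led_on, repeat_index = repeat_index,
                 sample_rate = sample_rate),
            class = "pr_trace")
}

#' @export
print.pr_trace <- function(x, ...) {
  cat(sprintf(
    "<pr_trace: %g nm, %.3g photons/cm2/s, LED %s, rep %d, %d samples @%g kHz>\n",
    x$wavelength_nm, x$intensity, if (x$led_on) "on" else "off",
    x$repeat_index, length(x$voltage_mV), x$sample_rate / 1000))
  invisible(x)
}

#' @export
plot.pr_trace <- function(x, ...) {
  graphics::plot(x$time_ms, x$voltage_mV, type = "l",
                 xlab = "Time (ms)", ylab = "Voltage (mV)", ...)
  graphics::abline(v = x$onset_ms, lty = 2, col = "grey50")
  invisible(x)
}

#' Simulate a full recording from one cell
#'
#' Runs the standard protocol: monochromatic flashes over `wavelengths`
#' (default 310-630 nm in 10 nm steps) with `repeats` presentations each,
#' followed by a V-log(I) series at the wavelength evoking the maximum
#' response (9 levels over 4 log units of attenuation). Optionally a
#' before/during/after adapting-LED block at the peak wavelength.
#'
#' @param cell A [sim_cell_spec()].
#' @param wavelengths Stimulus grid, nm.
#' @param repeats Repeats per stimulus (default 4).
#' @param intensity Isoquantal stimulus intensity (default 1.5e15).
#' @param vlogi_levels Number of V-log(I) intensity levels (default 9).
#' @param vlogi_span Attenuation range in log10 units (default 4).
#' @param led_protocol Add a before/during/after LED block at the peak
#'   wavelength (`repeats` presentations each)?
#' @param duration,onset,sample_rate Passed to [simulate_trace()].
#' @param cell_id,individual_id,group Metadata labels.
#' @return An object of class `"pr_recording"`: `spectral` (list of traces),
#'   `vlogi` (list of traces), optional `led` (`before`/`during`/`after`
#'   trace lists), the ground-truth `cell` spec and metadata.
#' @export
simulate_recording <- function(cell, wavelengths = seq(310, 630, by = 10),
                               repeats = 4, intensity = 1.5e15,
                               vlogi_levels = 9, vlogi_span = 4,
                               led_protocol = FALSE, duration = 1000,
                               onset = 500, flash_ms = 300,
                               sample_rate = 10000,
                               cell_id = "cell1", individual_id = "ind1",
                               group = "group1") {
  stopifnot(inherits(cell, "sim_cell_spec"))
  spectral <- list()
  for (w in wavelengths)
    for (r in seq_len(repeats))
      spectral[[length(spectral) + 1L]] <-
        simulate_trace(cell, w, intensity, duration = duration,
                       onset = onset, flash_ms = flash_ms,
                       sample_rate = sample_rate, repeat_index = r)
  # V-log(I) at the grid wavelength with the largest expected response
  tpl <- rhodopsin_template(cell$lambda_max, grid = wavelengths)
  w_peak <- peak_wavelength(tpl)
  lI <- seq(log10(intensity) - vlogi_span, log10(intensity),
            length.out = vlogi_levels)
  vlogi <- lapply(lI, function(l)
    simulate_trace(cell, w_peak, 10^l, duration = duration, onset = onset,
                   flash_ms = flash_ms, sample_rate = sample_rate))
  led <- NULL
  if (led_protocol) {
    run_block <- function(led_on, gain = 1) {
      lapply(seq_len(repeats), function(r) {
        tr <- simulate_trace(cell, w_peak, intensity, led_on = led_on,
                             duration = duration, onset = onset,
                             flash_ms = flash_ms,
                             sample_rate = sample_rate, repeat_index = r)
        if (gain != 1) {
          base <- cell$resting_potential
          tr$voltage_mV <- base + (tr$voltage_mV - base) * gain
        }
        tr
      })
    }
    led <- list(before = run_block(FALSE),
                during = run_block(TRUE),
                after = run_block(FALSE, gain = cell$led_recovery))
  }
  structure(list(spectral = spectral, vlogi = vlogi, led = led,
                 cell = cell, peak_stimulus_nm = w_peak,
                 wavelengths = wavelengths, repeats = repeats,
                 intensity = intensity, cell_id = cell_id,
                 individual_id = individual_id, group = group),
            class = "pr_recording")
}

#' @export
print.pr_recording <- function(x, ...) {
  cat(sprintf(
    "<pr_recording %s: %s/%s, %d wavelengths x %d repeats, %d V-log(I) levels%s>\n",
    x$cell_id, x$group, x$individual_id, length(x$wavelengths), x$repeats,
    length(x$vlogi), if (is.null(x$led)) "" else ", LED block"))
  invisible(x)
}

#' Default group layout for simulated experiments
#'
#' Seven groups of butterflies with the cell and individual counts of the
#' UV-photoreceptor dataset (43/12, 40/14, 18/9, 19/9, 8/4, 30/16, 22/10
#' cells/individuals) and per-group inhibition probabilities equal to the
#' pooled observed rates (yellow-preferring groups 0.708, no-preference
#' groups 0.468, white-preferring 0.167, outgroup males and females 0.192).
#'
#' @return A data.frame with columns `group`, `n_individuals`, `n_cells`,
#'   `p_inhibition`.
#' @export
default_experiment_groups <- function() {
  data.frame(
    group = c("cydno_white", "cydno_yellow", "galanthus", "f1_hybrid",
              "pachinus", "outgroup_males", "females"),
    n_individuals = c(12L, 14L, 9L, 9L, 4L, 16L, 10L),
    n_cells = c(43L, 40L, 18L, 19L, 8L, 30L, 22L),
    p_inhibition = c(0.468, 0.708, 0.167, 0.468, 0.708, 0.192, 0.192))
}

#' Specification of a simulated multi-group experiment
#'
#' @param groups Data.frame with columns `group`, `n_individuals`,
#'   `n_cells`, `p_inhibition` (default [default_experiment_groups()]).
#' @param cell_class Spectral class of the simulated cells (default "UV").
#' @param lambda_max_mean,lambda_max_sd Ground-truth lambda_max is drawn
#'   from a normal distribution truncated to `lambda_max_range` (UV default
#'   375 +/- 10 nm truncated to [345, 404], the observed continuous range).
#' @param lambda_max_range Truncation bounds, nm.
#' @param noise_sd Trace noise SD, mV.
#' @param wavelengths,repeats,intensity,vlogi_levels,vlogi_span,duration,onset,sample_rate
#'   Protocol parameters, see [simulate_recording()].
#' @param led_protocol Run the adapting-LED block for each cell?
#' @param seed Integer seed making the experiment reproducible.
#' @return An object of class `"sim_experiment_spec"`.
#' @export
sim_experiment_spec <- function(groups = default_experiment_groups(),
                                cell_class = "UV",
                                lambda_max_mean = 375, lambda_max_sd = 10,
                                lambda_max_range = c(345, 404),
                                noise_sd = 1.5,
                                wavelengths = seq(310, 630, by = 10),
                                repeats = 4, intensity = 1.5e15,
                                vlogi_levels = 9, vlogi_span = 4,
                                led_protocol = FALSE,
                                duration = 1000, onset = 500,
                                flash_ms = 300,
                                sample_rate = 10000, seed = 1L) {
  need <- c("group", "n_individuals", "n_cells", "p_inhibition")
  if (!all(need %in% names(groups)))
    stop("groups must have columns ", paste(need, collapse = ", "))
  if (any(groups$p_inhibition < 0 | groups$p_inhibition > 1))
    stop("p_inhibition must be in [0, 1]")
  if (any(groups$n_cells < groups$n_individuals))
    stop("each individual must contribute at least one cell")
  structure(list(groups = groups, cell_class = cell_class,
                 lambda_max_mean = lambda_max_mean,
                 lambda_max_sd = lambda_max_sd,
                 lambda_max_range = lambda_max_range, noise_sd = noise_sd,
                 wavelengths = wavelengths, repeats = repeats,
                 intensity = intensity, vlogi_levels = vlogi_levels,
                 vlogi_span = vlogi_span, led_protocol = led_protocol,
                 duration = duration, onset = onset, flash_ms = flash_ms,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "sim_experiment_spec")
}

# Draw the ground-truth cell table (ids, lambda_max, inhibition flags)
# without generating traces. Used by simulate_experiment and by the
# streaming pipeline.
draw_truth_table <- function(spec) {
  g <- spec$groups
  rows <- list()
  for (i in seq_len(nrow(g))) {
    n <- g$n_cells[i]
    ind <- sprintf("%s_ind%02d", g$group[i],
                   sort(rep_len(seq_len(g$n_individuals[i]), n)))
    lm <- stats::rnorm(n, spec$lambda_max_mean, spec$lambda_max_sd)
    lm <- pmin(pmax(lm, spec$lambda_max_range[1]), spec$lambda_max_range[2])
    rows[[i]] <- data.frame(
      cell_id = sprintf("%s_c%03d", g$group[i], seq_len(n)),
      individual_id = ind, group = g$group[i],
      cell_class = spec$cell_class, lambda_max = lm,
      inhibited = stats::runif(n) < g$p_inhibition[i])
  }
  do.call(rbind, rows)
}

cell_spec_from_truth <- function(spec, row) {
  sim_cell_spec(row$cell_class, lambda_max = row$lambda_max,
                inhibited = row$inhibited, noise_sd = spec$noise_sd)
}

#' Simulate a multi-group experiment
#'
#' Draws ground truth (individual assignment, lambda_max, inhibition
#' status) for every cell and generates the full set of recordings. The
#' same seed gives identical output. Note a full-size default experiment
#' holds ~180 recordings of ~10 MB each in memory; use
#' [run_pipeline()] with a simulation config to analyze cells one at a
#' time instead, or shrink the protocol.
#'
#' @param spec A [sim_experiment_spec()].
#' @return A list with `recordings` (list of [simulate_recording()]
#'   results) and `truth` (data.frame of ground-truth labels per cell).
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "sim_experiment_spec"))
  set.seed(spec$seed)
  truth <- draw_truth_table(spec)
  recordings <- lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    simulate_recording(cell_spec_from_truth(spec, row),
                       wavelengths = spec$wavelengths,
                       repeats = spec$repeats, intensity = spec$intensity,
                       vlogi_levels = spec$vlogi_levels,
                       vlogi_span = spec$vlogi_span,
                       led_protocol = spec$led_protocol,
                       duration = spec$duration, onset = spec$onset,
                       flash_ms = spec$flash_ms,
                       sample_rate = spec$sample_rate,
                       cell_id = row$cell_id,
                       individual_id = row$individual_id,
                       group = row$group)
  })
  list(recordings = recordings, truth = truth)
}

#' Synthetic wing reflectance spectra
#'
#' White wings reflect strongly across 300-700 nm, including the UV; yellow
#' wings are near-zero below a ~420 nm cutoff and reflect strongly above
#' it, with a smooth sigmoidal edge. The long-wavelength plateau is the
#' same for both colors.
#'
#' @param color `"white"` or `"yellow"`.
#' @param grid Wavelength grid spanning 300-700 nm.
#' @param cutoff Yellow edge position, nm (default 420).
#' @param edge_width Sigmoid scale of the edge, nm (default 8).
#' @param plateau Long-wavelength reflectance level (default 0.9).
#' @return A [spectrum()] of kind `"reflectance"`.
#' @export
simulate_wing_reflectance <- function(color, grid = seq(300, 700, by = 1),
                                      cutoff = 420, edge_width = 8,
                                      plateau = 0.9) {
  if (min(grid) > 300 || max(grid) < 700)
    stop("grid must span 300-700 nm")
  color <- match.arg(color, c("white", "yellow"))
  v <- switch(color,
    white = plateau * (1 - 0.05 * exp(-(grid - 700) ^ 2 / 2e5)),
    yellow = plateau / (1 + exp(-(grid - cutoff) / edge_width)))
  spectrum(grid, v, "reflectance")
}

#' Simulate a measured spectral sensitivity curve
#'
#' Sensitivity-level generator for template-fitting studies: the rhodopsin
#' template at `lambda_max` evaluated on the measurement grid plus additive
#' Gaussian noise on the normalized scale.
#'
#' @param lambda_max True peak, nm.
#' @param grid Measurement grid (default 310-630 nm in 10 nm steps).
#' @param noise_sd SD of the additive noise on the normalized sensitivity
#'   (0 = exact template).
#' @return A [spectrum()] of kind `"sensitivity"`. Values can dip below 0
#'   at noisy tail wavelengths; [fit_lambda_max()] ignores non-positive
#'   bins.
#' @export
simulate_sensitivity <- function(lambda_max, grid = seq(310, 630, by = 10),
                                 noise_sd = 0) {
  tpl <- rhodopsin_template(lambda_max, grid = grid)
  v <- tpl$value + stats::rnorm(length(grid), 0, noise_sd)
  spectrum(grid, v, "response")
}
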