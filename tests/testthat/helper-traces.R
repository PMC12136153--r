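# Hand-built traces with known geometry, for feature-extraction oracles.
# 10 kHz sampling, onset at 500 ms unless stated otherwise.

make_trace <- function(voltage, onset = 500, sample_rate = 10000,
                       wavelength = 400, intensity = 1.5e15,
                       led_on = FALSE) {
  dt <- 1000 / sample_rate
  structure(list(time_ms = seq(0, by = dt, length.out = length(voltage)),
                 voltage_mV = voltage, onset_ms = onset,
                 wavelength_nm = wavelength, intensity = intensity,
                 led_on = led_on, repeat_index = 1L,
                 sample_rate = sample_rate),
            class = "pr_trace")
}

# constant baseline `base`, then `shape(t_post)` added from onset onward
make_shaped_trace <- function(shape, base = -52.7, duration = 1000,
                              onset = 500, sample_rate = 10000, ...) {
  dt <- 1000 / sample_rate
  t <- seq(0, duration - dt, by = dt)
  v <- rep(base, length(t))
  post <- t >= onset
  v[post] <- base + shape(t[post] - onset)
  make_trace(v, onset = onset, sample_rate = sample_rate, ...)
}

feature_row <- function(amplitude, baseline_mean = -52.7,
                        baseline_sd = 0.4, wavelength = 370,
                        latency = 20) {
  data.frame(wavelength_nm = wavelength, intensity = 1.5e15,
             led_on = FALSE, n_repeats = 4,
             baseline_mean_mV = baseline_mean,
             baseline_sd_mV = baseline_sd, baseline_drift_mV_s = 0,
             amplitude_mV = amplitude,
             polarity = if (amplitude >= 0) "depolarizing"
               else "hyperpolarizing",
             latency_ms = latency, halfmax_ms = 60)
}
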