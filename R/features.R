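#' Baseline statistics of a trace
#'
#' Mean and standard deviation of the membrane potential over exactly the
#' 500 ms (by default) window ending at stimulus onset. Samples at or after
#' onset are never included.
#'
#' @param trace A `"pr_trace"` (see [simulate_trace()]).
#' @param window Baseline window length, ms (default 500).
#' @return List with `mean`, `sd` (mV) and `drift` (linear trend, mV/s).
#' @export
baseline_stats <- function(trace, window = 500) {
  stopifnot(inherits(trace, "pr_trace"))
  if (trace$onset_ms < window)
    stop("insufficient pre-onset baseline: need ", window, " ms")
  i <- trace$time_ms >= (trace$onset_ms - window) &
    trace$time_ms < trace$onset_ms
  v <- trace$voltage_mV[i]
  t <- trace$time_ms[i]
  drift <- 1000 * stats::cov(t, v) / stats::var(t)  # mV/s
  list(mean = mean(v), sd = stats::sd(v), drift = drift)
}

#' Response onset latency
#'
#' Latency is the time after stimulus onset at which the voltage first
#' departs from the baseline mean by more than `threshold_mult` (default 5)
#' baseline standard deviations, sustained for at least `debounce` ms: the
#' time of the first supra-threshold sample (resolution one sample,
#' 0.1 ms at 10 kHz). The sign of the crossing sets the response polarity.
#' Returns latency `NA` (polarity `"none"`) if the threshold is never
#' crossed.
#'
#' The debounce guards against single-sample noise excursions: at 10 kHz a
#' 5 sigma sample occurs by chance about once per 1.7 s of Gaussian noise.
#' A `sd_floor` (default 0.05 mV) substitutes for pathological zero-noise
#' baselines.
#'
#' @param trace A `"pr_trace"`.
#' @param baseline Optional precomputed [baseline_stats()] result.
#' @param threshold_mult Threshold in baseline SDs (default 5).
#' @param debounce Minimum supra-threshold duration, ms (default 1).
#' @param sd_floor Lower bound on the baseline SD used for the threshold.
#' @param window Search window after onset, ms (default 500).
#' @return List with `latency_ms` (NA if no crossing) and `polarity`
#'   (`"depolarizing"`, `"hyperpolarizing"` or `"none"`).
#' @export
onset_latency <- function(trace, baseline = NULL, threshold_mult = 5,
                          debounce = 1, sd_floor = 0.05, window = 500) {
  stopifnot(inherits(trace, "pr_trace"))
  if (is.null(baseline)) baseline <- baseline_stats(trace)
  thr <- threshold_mult * max(baseline$sd, sd_floor)
  dt <- 1000 / trace$sample_rate
  post <- trace$time_ms >= trace$onset_ms &
    trace$time_ms <= trace$onset_ms + window
  dev <- trace$voltage_mV[post] - baseline$mean
  t <- trace$time_ms[post]
  above <- abs(dev) > thr
  need <- max(1L, as.integer(round(debounce / dt)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0L)
    return(list(latency_ms = NA_real_, polarity = "none"))
  i <- ends[ok[1]] - r$lengths[ok[1]] + 1L  # first sample of the run
  list(latency_ms = t[i] - trace$onset_ms,
       polarity = if (dev[i] > 0) "depolarizing" else "hyperpolarizing")
}

#' Response amplitude and polarity
#'
#' Signed amplitude: the extremum of the voltage deviation from the
#' baseline mean within the post-onset window (depolarizing positive),
#' after a short moving-average smoothing (`smooth_ms`, default 2 ms).
#' Without smoothing the extremum of a long window rides on the extremum
#' of the sample noise, biasing every amplitude upward by several noise
#' SDs; a 2 ms boxcar is much shorter than the response kinetics and
#' removes most of that bias. The polarity is `"none"` when the extremum
#' stays within `threshold_mult` baseline SDs.
#'
#' @inheritParams onset_latency
#' @param smooth_ms Moving-average width before the extremum, ms
#'   (0 disables).
#' @return List with `amplitude_mV` (signed) and `polarity`.
#' @export
response_amplitude <- function(trace, baseline = NULL, threshold_mult = 5,
                               sd_floor = 0.05, window = 500,
                               smooth_ms = 2) {
  stopifnot(inherits(trace, "pr_trace"))
  if (is.null(baseline)) baseline <- baseline_stats(trace)
  post <- trace$time_ms >= trace$onset_ms &
    trace$time_ms <= trace$onset_ms + window
  dev <- trace$voltage_mV[post] - baseline$mean
  k <- as.integer(round(smooth_ms * trace$sample_rate / 1000))
  if (k > 1L && length(dev) > k) {
    sm <- stats::filter(dev, rep(1 / k, k), sides = 2)
    dev <- as.numeric(sm[!is.na(sm)])
  }
  amp <- dev[which.max(abs(dev))]
  thr <- threshold_mult * max(baseline$sd, sd_floor)
  pol <- if (abs(amp) <= thr) "none"
    else if (amp > 0) "depolarizing" else "hyperpolarizing"
  list(amplitude_mV = amp, polarity = pol)
}

#' Half-maximum response duration
#'
#' Total time the depolarizing response stays above 50% of its maximum,
#' summed over all supra-half-max intervals with linear interpolation at
#' the crossings. `NA` when there is no depolarizing response.
#'
#' @inheritParams onset_latency
#' @return Duration in ms, or `NA`.
#' @export
halfmax_duration <- function(trace, baseline = NULL, window = 500) {
  stopifnot(inherits(trace, "pr_trace"))
  if (is.null(baseline)) baseline <- baseline_stats(trace)
  post <- trace$time_ms >= trace$onset_ms &
    trace$time_ms <= trace$onset_ms + window
  dev <- trace$voltage_mV[post] - baseline$mean
  peak <- max(dev)
  if (peak <= 0) return(NA_real_)
  dt <- 1000 / trace$sample_rate
  half <- peak / 2
  above <- dev >= half
  if (!any(above)) return(NA_real_)
  # sum sample intervals, refining each boundary by interpolation
  total <- 0
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- (i1 - i0) * dt
    if (i0 > 1L)
      seg <- seg + dt * (dev[i0] - half) / (dev[i0] - dev[i0 - 1L])
    if (i1 < length(dev))
      seg <- seg + dt * (dev[i1] - half) / (dev[i1] - dev[i1 + 1L])
    total <- total + seg
  }
  total
}

#' Average repeated presentations of the same stimulus
#'
#' @param traces List of `"pr_trace"` objects with identical time grids and
#'   stimulus metadata.
#' @return One `"pr_trace"` whose voltage is the pointwise mean.
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "pr_trace")))
  n <- vapply(traces, function(x) length(x$voltage_mV), integer(1))
  if (length(unique(n)) != 1L) stop("traces differ in length")
  out <- traces[[1L]]
  out$voltage_mV <- rowMeans(vapply(traces, `[[`, numeric(n[1]),
                                    "voltage_mV"))
  out$repeat_index <- NA_integer_
  out
}

#' Full feature set for one stimulus condition
#'
#' Extracts baseline statistics, signed amplitude, polarity, onset latency
#' and half-max duration from the repeat-averaged trace of one
#' (wavelength, intensity, LED) condition.
#'
#' @param traces A single `"pr_trace"` or a list of repeats to average.
#' @param window Post-onset analysis window, ms.
#' @return A one-row data.frame (wavelength_nm, intensity, led_on,
#'   n_repeats, baseline_mean_mV, baseline_sd_mV, baseline_drift_mV_s,
#'   amplitude_mV, polarity, latency_ms, halfmax_ms).
#' @export
trace_features <- function(traces, window = 500) {
  if (inherits(traces, "pr_trace")) traces <- list(traces)
  avg <- average_traces(traces)
  base <- baseline_stats(avg)
  amp <- response_amplitude(avg, base, window = window)
  lat <- onset_latency(avg, base, window = window)
  hm <- if (amp$polarity == "depolarizing")
    halfmax_duration(avg, base, window = window) else NA_real_
  data.frame(wavelength_nm = avg$wavelength_nm, intensity = avg$intensity,
             led_on = avg$led_on, n_repeats = length(traces),
             baseline_mean_mV = base$mean, baseline_sd_mV = base$sd,
             baseline_drift_mV_s = base$drift,
             amplitude_mV = amp$amplitude_mV, polarity = amp$polarity,
             latency_ms = lat$latency_ms, halfmax_ms = hm)
}

#' Adaptation deltas from a before/during/after LED block
#'
#' Quantifies the effect of the adapting LED at the cell's peak wavelength:
#' the resting-potential shift (during minus before), the response
#' amplitude ratio (during / before) and the recovery fraction
#' (after / before). Cells recovering less than `recovery_min` of the
#' original response fail quality control.
#'
#' @param before,during,after One-row feature data.frames from
#'   [trace_features()], all at the same stimulus wavelength.
#' @param recovery_min QC threshold on the recovery fraction (default 0.8).
#' @return List with `delta_resting_mV`, `amplitude_ratio`,
#'   `recovery_fraction`, `qc_pass`.
#' @export
adaptation_deltas <- function(before, during, after, recovery_min = 0.8) {
  for (ph in list(before, during, after))
    if (!is.data.frame(ph) || nrow(ph) != 1L)
      stop("each phase must be a one-row feature data.frame")
  if (length(unique(c(before$wavelength_nm, during$wavelength_nm,
                      after$wavelength_nm))) != 1L)
    stop("all three phases must be measured at the same wavelength")
  ratio <- during$amplitude_mV / before$amplitude_mV
  recovery <- after$amplitude_mV / before$amplitude_mV
  list(delta_resting_mV = during$baseline_mean_mV - before$baseline_mean_mV,
       amplitude_ratio = ratio,
       recovery_fraction = recovery,
       qc_pass = is.finite(recovery) && recovery >= recovery_min)
}

#' Cell-level quality control
#'
#' A cell passes when its maximum depolarizing response is at least
#' `min_depol` (30 mV: all healthy photoreceptors respond to strong light
#' with depolarizations of at least 30 mV), the LED recovery fraction (when
#' an LED block was run) is at least `recovery_min`, and the baseline drift
#' stays within `max_drift`.
#'
#' @param max_depol_mV Largest depolarizing amplitude observed for the
#'   cell, mV.
#' @param recovery_fraction LED recovery fraction, or `NA` if no LED block.
#' @param baseline_drift_mV_s Baseline linear trend, mV/s, or `NA`.
#' @param min_depol Amplitude criterion, mV (default 30).
#' @param recovery_min Recovery criterion (default 0.8).
#' @param max_drift Drift criterion, mV/s (default 10).
#' @return List with `pass` (logical) and `reasons` (character vector,
#'   empty when passing; values among "amplitude", "recovery", "drift").
#' @export
qc_cell <- function(max_depol_mV, recovery_fraction = NA,
                    baseline_drift_mV_s = NA, min_depol = 30,
                    recovery_min = 0.8, max_drift = 10) {
  reasons <- character(0)
  if (!is.finite(max_depol_mV) || max_depol_mV < min_depol)
    reasons <- c(reasons, "amplitude")
  if (is.finite(recovery_fraction) && recovery_fraction < recovery_min)
    reasons <- c(reasons, "recovery")
  if (is.finite(baseline_drift_mV_s) &&
      abs(baseline_drift_mV_s) > max_drift)
    reasons <- c(reasons, "drift")
  list(pass = length(reasons) == 0L, reasons = reasons)
}
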