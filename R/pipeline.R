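#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one place. Defaults
#' are the recording-protocol values the rest of the package documents:
#' 30 mV minimum saturating depolarization, 80% LED recovery, 5 baseline
#' SDs for response detection, 530/590 nm inhibition probes, class
#' boundaries at 420/500/580 nm.
#'
#' @param experiment A [sim_experiment_spec()] (simulate-and-analyze mode),
#'   or `NULL` when reading traces from `input_dir`.
#' @param input_dir Directory produced by [make_fixtures()] (or matching
#'   its manifest layout).
#' @param min_depol QC amplitude criterion, mV.
#' @param recovery_min QC LED recovery criterion.
#' @param max_drift QC baseline drift bound, mV/s.
#' @param threshold_mult Response detection threshold, baseline SDs.
#' @param sd_floor Baseline SD floor, mV.
#' @param window Post-onset analysis window, ms.
#' @param r2_floor Template-fit reliability floor.
#' @param boundaries Spectral class boundaries, nm.
#' @param search Template-fit search range, nm.
#' @param seed Seed used for any stochastic analysis step.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(experiment = NULL, input_dir = NULL,
                            min_depol = 30, recovery_min = 0.8,
                            max_drift = 10, threshold_mult = 5,
                            sd_floor = 0.05, window = 500,
                            r2_floor = 0.5,
                            boundaries = c(330, 420, 500, 580),
                            search = c(330, 650), seed = 1L) {
  stopifnot(min_depol > 0, recovery_min > 0, max_drift > 0,
            threshold_mult > 0, window > 0)
  structure(list(experiment = experiment, input_dir = input_dir,
                 min_depol = min_depol, recovery_min = recovery_min,
                 max_drift = max_drift, threshold_mult = threshold_mult,
                 sd_floor = sd_floor, window = window,
                 r2_floor = r2_floor, boundaries = boundaries,
                 search = search, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$experiment)) {
    ex <- unclass(x$experiment)
    ex$groups <- as.list(ex$groups)
    x$experiment <- ex
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  ex <- NULL
  if (!is.null(x$experiment)) {
    exl <- x$experiment
    exl$groups <- as.data.frame(exl$groups)
    ex <- do.call(sim_experiment_spec, exl)
  }
  x$experiment <- NULL
  do.call(pipeline_config, c(list(experiment = ex), x))
}

#' Analyze one cell recording
#'
#' Runs the per-cell chain: repeat-averaged feature extraction at every
#' wavelength, Naka-Rushton fit of the V-log(I) series, inversion to a
#' spectral sensitivity curve, template fit of lambda_max, spectral class
#' assignment, inhibition scoring at the class probe wavelength, LED
#' adaptation deltas (when recorded), and quality control.
#'
#' @param rec A `"pr_recording"` (see [simulate_recording()]; recordings
#'   read from disk have the same structure).
#' @param config A [pipeline_config()].
#' @return A one-row data.frame (the cells-table row), with the feature
#'   table, sensitivity spectrum and fits attached as attributes
#'   `features`, `sensitivity`, `nr_fit`, `template_fit`.
#' @export
analyze_recording <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "pr_recording"))
  # repeat-averaged features per wavelength
  wl <- vapply(rec$spectral, `[[`, numeric(1), "wavelength_nm")
  feats <- do.call(rbind, lapply(unique(wl), function(w) {
    trace_features(rec$spectral[wl == w], window = config$window)
  }))
  feats <- feats[order(feats$wavelength_nm), ]
  # V-log(I) series and Naka-Rushton fit
  vfeat <- do.call(rbind, lapply(rec$vlogi, trace_features,
                                 window = config$window))
  noise_sd <- stats::median(feats$baseline_sd_mV)
  nr <- fit_naka_rushton(log10(vfeat$intensity), vfeat$amplitude_mV,
                         wavelength = vfeat$wavelength_nm[1],
                         noise_sd = noise_sd)
  # sensitivity + lambda_max
  tfit <- NULL
  sens <- NULL
  cls <- "unknown"
  if (nr$converged) {
    sens <- responses_to_sensitivity(
      data.frame(wavelength_nm = feats$wavelength_nm,
                 amplitude_mV = feats$amplitude_mV),
      nr, isoquantal_intensity = rec$intensity)
    tfit <- fit_lambda_max(sens, search = config$search,
                           r2_floor = config$r2_floor)
    cls <- classify_photoreceptor(tfit, sens,
                                  boundaries = config$boundaries)
  }
  # inhibition at the class probe wavelength
  lmax_row <- feats[which.max(feats$amplitude_mV), ]
  inh <- list(inhibited = NA, inhibition_amplitude = NA_real_,
              probe_latency_ms = NA_real_,
              lmax_latency_ms = lmax_row$latency_ms)
  if (cls %in% c("UV", "blue")) {
    pw <- probe_wavelength(cls)
    probe_row <- feats[feats$wavelength_nm == pw, ]
    inh <- classify_inhibition(
      if (nrow(probe_row) == 1L) probe_row else NULL, lmax_row,
      threshold_mult = config$threshold_mult,
      sd_floor = config$sd_floor)
  }
  # LED adaptation block
  ad <- list(delta_resting_mV = NA_real_, amplitude_ratio = NA_real_,
             recovery_fraction = NA_real_)
  if (!is.null(rec$led)) {
    ad <- adaptation_deltas(trace_features(rec$led$before),
                            trace_features(rec$led$during),
                            trace_features(rec$led$after),
                            recovery_min = config$recovery_min)
  }
  qc <- qc_cell(max(feats$amplitude_mV), ad$recovery_fraction,
                lmax_row$baseline_drift_mV_s,
                min_depol = config$min_depol,
                recovery_min = config$recovery_min,
                max_drift = config$max_drift)
  row <- data.frame(
    cell_id = rec$cell_id, individual_id = rec$individual_id,
    group = rec$group, cell_class = cls,
    lambda_max_nm = if (!is.null(tfit)) tfit$lambda_max else NA_real_,
    r2 = if (!is.null(tfit)) tfit$r2 else NA_real_,
    v_max = nr$v_max, n = nr$n, log10_K = nr$log10_K,
    inhibited = inh$inhibited,
    inhibition_amplitude = inh$inhibition_amplitude,
    probe_latency_ms = inh$probe_latency_ms,
    lmax_latency_ms = inh$lmax_latency_ms,
    halfmax_ms = lmax_row$halfmax_ms,
    max_depol_mV = max(feats$amplitude_mV),
    resting_mV = lmax_row$baseline_mean_mV,
    delta_resting_mV = ad$delta_resting_mV,
    amplitude_ratio = ad$amplitude_ratio,
    recovery_fraction = ad$recovery_fraction,
    qc_pass = qc$pass,
    qc_reasons = paste(qc$reasons, collapse = ";"))
  attr(row, "features") <- feats
  attr(row, "sensitivity") <- sens
  attr(row, "nr_fit") <- nr
  attr(row, "template_fit") <- tfit
  row
}

# Group-level statistics from an analyzed cells table (QC-passing cells
# with a defined inhibition label)
summarize_groups <- function(cells) {
  use <- cells[cells$qc_pass & !is.na(cells$inhibited), ]
  out <- list(proportions = NULL, pairwise = NULL, lambda_max_model = NULL)
  if (nrow(use) == 0L) return(out)
  agg <- do.call(rbind, lapply(split(use, use$group), function(d) {
    proportion_with_sem(sum(d$inhibited), nrow(d), group = d$group[1],
                        n_individuals = length(unique(d$individual_id)))
  }))
  rownames(agg) <- NULL
  out$proportions <- agg
  if (length(unique(use$group)) >= 2L) {
    out$pairwise <- tryCatch(
      pairwise_group_tests(use, outcome = "inhibited", link = "logit"),
      error = function(e) NULL)
    out$lambda_max_model <- tryCatch(
      fit_linear_mixed(use, outcome = "lambda_max_nm")$coefficients,
      error = function(e) NULL)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Either simulates an experiment cell by cell (memory stays flat: each
#' recording is analyzed and discarded) or reads one from `input_dir`,
#' then extracts features, fits sensitivities, classifies cells, computes
#' group-level inhibition statistics, and runs the wing-color perception
#' sweep over the observed UV lambda_max range. With `out_dir` set, writes
#' `cells.csv` and `report.json`.
#'
#' @param config A [pipeline_config()] with either `experiment` or
#'   `input_dir` set.
#' @param out_dir Optional output directory.
#' @param progress Print a progress line per cell?
#' @return The report: a list with `provenance`, `qc`, `cells`
#'   (data.frame), `groups` (proportions, pairwise tests, lambda_max
#'   model) and `perception`.
#' @export
run_pipeline <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$experiment) && is.null(config$input_dir))
    stop("config needs either an experiment spec or an input_dir")
  if (!is.null(config$experiment)) {
    spec <- config$experiment
    set.seed(spec$seed)
    truth <- draw_truth_table(spec)
    n <- nrow(truth)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      row <- truth[i, ]
      rec <- simulate_recording(
        cell_spec_from_truth(spec, row),
        wavelengths = spec$wavelengths, repeats = spec$repeats,
        intensity = spec$intensity, vlogi_levels = spec$vlogi_levels,
        vlogi_span = spec$vlogi_span, led_protocol = spec$led_protocol,
        duration = spec$duration, onset = spec$onset,
        sample_rate = spec$sample_rate, cell_id = row$cell_id,
        individual_id = row$individual_id, group = row$group)
      rows[[i]] <- analyze_recording(rec, config)
      attributes(rows[[i]])[c("features", "sensitivity", "nr_fit",
                              "template_fit")] <- NULL
      if (progress)
        message(sprintf("[%d/%d] %s", i, n, row$cell_id))
    }
    cells <- do.call(rbind, rows)
  } else {
    exp <- read_experiment(config$input_dir)
    truth <- exp$truth
    cells <- do.call(rbind, lapply(exp$recordings, function(rec) {
      r <- analyze_recording(rec, config)
      attributes(r)[c("features", "sensitivity", "nr_fit",
                      "template_fit")] <- NULL
      r
    }))
  }
  rownames(cells) <- NULL
  groups <- summarize_groups(cells)
  perception <- NULL
  uv <- cells[cells$qc_pass & cells$cell_class == "UV" &
                is.finite(cells$lambda_max_nm), ]
  if (nrow(uv) >= 2L) {
    rng <- range(uv$lambda_max_nm)
    perception <- excitation_sweep(
      list(white = simulate_wing_reflectance("white"),
           yellow = simulate_wing_reflectance("yellow")),
      seq(rng[1], rng[2], length.out = 5))
  }
  report <- list(
    provenance = list(
      package = "specsens",
      version = as.character(utils::packageVersion("specsens")),
      r_version = R.version.string,
      seed = if (!is.null(config$experiment)) config$experiment$seed
        else config$seed,
      schema_version = 1L,
      n_cells = nrow(cells)),
    qc = list(n_cells = nrow(cells), n_pass = sum(cells$qc_pass),
              reasons = table(cells$qc_reasons[cells$qc_reasons != ""])),
    cells = cells, truth = truth, groups = groups,
    perception = perception)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    json <- report
    json$cells <- NULL
    json$truth <- NULL
    json$qc$reasons <- as.list(json$qc$reasons)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}

#' Write a miniature on-disk experiment for tests and demos
#'
#' Simulates a small multi-group experiment and writes it in the exchange
#' layout the pipeline reads back: one TSV per presentation
#' (`time_ms`, `voltage_mV`), a `manifest.csv` of presentation metadata,
#' and a ground-truth `truth.csv`. With `scale = 0` only the metadata
#' skeleton is written.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param scale Size multiplier: cells per individual is
#'   `max(1, round(2 * scale))`; `scale = 0` writes metadata only.
#' @return `dir`, invisibly. The directory holds ~15 MB of traces at
#'   `scale = 1`.
#' @export
make_fixtures <- function(dir, seed = 1L, scale = 1) {
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  cells_per_ind <- max(1L, as.integer(round(2 * scale)))
  groups <- data.frame(
    group = c("high_inh", "low_inh"), n_individuals = c(2L, 2L),
    n_cells = 2L * cells_per_ind, p_inhibition = c(0.9, 0.1))
  # coarse spectral grid, but keep the 530 nm inhibition probe on it
  wl <- sort(unique(c(seq(310, 630, by = 40), 530)))
  spec <- sim_experiment_spec(
    groups = groups, wavelengths = wl, repeats = 2,
    vlogi_levels = 5, duration = 700, onset = 500, flash_ms = 150,
    seed = seed)
  set.seed(spec$seed)
  truth <- draw_truth_table(spec)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  manifest <- list()
  if (scale > 0) {
    fi <- 0L
    for (i in seq_len(nrow(truth))) {
      row <- truth[i, ]
      rec <- simulate_recording(
        cell_spec_from_truth(spec, row), wavelengths = spec$wavelengths,
        repeats = spec$repeats, intensity = spec$intensity,
        vlogi_levels = spec$vlogi_levels, vlogi_span = spec$vlogi_span,
        duration = spec$duration, onset = spec$onset,
        flash_ms = spec$flash_ms,
        cell_id = row$cell_id, individual_id = row$individual_id,
        group = row$group)
      for (kind in c("spectral", "vlogi")) {
        for (tr in rec[[kind]]) {
          fi <- fi + 1L
          f <- sprintf("traces/trace_%06d.tsv", fi)
          utils::write.table(
            data.frame(time_ms = sprintf("%.1f", tr$time_ms),
                       voltage_mV = sprintf("%.3f", tr$voltage_mV)),
            file.path(dir, f), sep = "\t", row.names = FALSE,
            quote = FALSE)
          manifest[[fi]] <- data.frame(
            file = f, cell_id = row$cell_id,
            individual_id = row$individual_id, group = row$group,
            kind = kind, wavelength_nm = tr$wavelength_nm,
            intensity = tr$intensity, led = tr$led_on,
            repeat_index = tr$repeat_index, onset_ms = tr$onset_ms,
            sample_rate = tr$sample_rate)
        }
      }
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(file = character(0), cell_id = character(0),
               individual_id = character(0), group = character(0),
               kind = character(0), wavelength_nm = numeric(0),
               intensity = numeric(0), led = logical(0),
               repeat_index = integer(0), onset_ms = numeric(0),
               sample_rate = numeric(0))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an on-disk experiment written by [make_fixtures()]
#'
#' @param dir Directory with `manifest.csv`, `truth.csv` and `traces/`.
#' @return List with `recordings` (list of `"pr_recording"`) and `truth`.
#' @export
read_experiment <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf)
  if (nrow(manifest) == 0L) stop("manifest is empty: no traces to analyze")
  truth <- if (file.exists(file.path(dir, "truth.csv")))
    utils::read.csv(file.path(dir, "truth.csv")) else NULL
  read_trace <- function(row) {
    d <- utils::read.delim(file.path(dir, row$file))
    structure(list(time_ms = d$time_ms, voltage_mV = d$voltage_mV,
                   onset_ms = row$onset_ms,
                   wavelength_nm = row$wavelength_nm,
                   intensity = row$intensity, led_on = row$led,
                   repeat_index = row$repeat_index,
                   sample_rate = row$sample_rate),
              class = "pr_trace")
  }
  recordings <- lapply(split(manifest, manifest$cell_id), function(m) {
    traces <- lapply(seq_len(nrow(m)), function(i) read_trace(m[i, ]))
    spectral <- traces[m$kind == "spectral"]
    vlogi <- traces[m$kind == "vlogi"]
    wls <- sort(unique(m$wavelength_nm[m$kind == "spectral"]))
    structure(list(spectral = spectral, vlogi = vlogi, led = NULL,
                   cell = NULL,
                   peak_stimulus_nm = vlogi[[1]]$wavelength_nm,
                   wavelengths = wls,
                   repeats = max(m$repeat_index[m$kind == "spectral"]),
                   intensity = max(m$intensity),
                   cell_id = m$cell_id[1],
                   individual_id = m$individual_id[1],
                   group = m$group[1]),
              class = "pr_recording")
  })
  list(recordings = recordings, truth = truth)
}
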