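#' Fit the Naka-Rushton function to a V-log(I) series
#'
#' Least-squares fit of the saturating intensity-response function
#' \deqn{V(I) = V_{max} I^n / (I^n + K^n)}
#' to response amplitudes measured at graded intensities of a single
#' wavelength. By definition `V(K) = v_max / 2`. Fitting is done on the
#' log10 intensity scale with Levenberg-Marquardt least squares.
#'
#' @param log10_intensity Numeric vector, log10 photon flux of each level.
#' @param response Mean response amplitude at each level, mV.
#' @param wavelength Wavelength at which the series was measured (metadata).
#' @param noise_sd Optional baseline noise SD; the fit is flagged when the
#'   largest response is below 5 x this value.
#' @return An object of class `"naka_rushton"` with elements `v_max`,
#'   `log10_K`, `n`, `rss`, `converged`, `flags`, plus the data. A
#'   degenerate series (too few levels, decreasing trend, no usable
#'   dynamic range) gives `converged = FALSE` with a reason in `flags`
#'   rather than an error.
#' @examples
#' lI <- seq(11, 15, length.out = 9)
#' v <- 40 / (1 + 10^(1 * (13.5 - lI)))
#' fit <- fit_naka_rushton(lI, v)
#' coef(fit)
#' @export
fit_naka_rushton <- function(log10_intensity, response, wavelength = NA,
                             noise_sd = NULL) {
  ok <- is.finite(log10_intensity) & is.finite(response)
  log10_intensity <- log10_intensity[ok]
  response <- response[ok]
  flags <- character(0)
  fail <- function(why) {
    structure(list(v_max = NA_real_, log10_K = NA_real_, n = NA_real_,
                   rss = NA_real_, converged = FALSE, flags = why,
                   wavelength = wavelength,
                   data = data.frame(log10_intensity = log10_intensity,
                                     response = response)),
              class = "naka_rushton")
  }
  if (length(response) < 5L) return(fail("too_few_levels"))
  if (!is.null(noise_sd) && max(response) <= 5 * noise_sd)
    return(fail("low_snr"))
  if (stats::cor(log10_intensity, response, method = "spearman") <= 0)
    return(fail("non_monotone"))
  vmax0 <- 1.05 * max(response)
  lK0 <- stats::approx(response, log10_intensity,
                       xout = vmax0 / 2, ties = mean, rule = 2)$y
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ vmax / (1 + 10^(n * (lK - log10_intensity))),
      start = list(vmax = vmax0, lK = lK0, n = 1),
      lower = c(vmax = 1e-6, lK = min(log10_intensity) - 4, n = 0.05),
      upper = c(vmax = 10 * vmax0, lK = max(log10_intensity) + 4, n = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("no_convergence"))
  cf <- stats::coef(fit)
  structure(list(v_max = unname(cf["vmax"]), log10_K = unname(cf["lK"]),
                 n = unname(cf["n"]),
                 rss = sum(stats::residuals(fit)^2),
                 converged = TRUE, flags = flags, wavelength = wavelength,
                 data = data.frame(log10_intensity = log10_intensity,
                                   response = response)),
            class = "naka_rushton")
}

#' @export
print.naka_rushton <- function(x, ...) {
  if (!x$converged) {
    cat("<naka_rushton: fit failed (", paste(x$flags, collapse = ", "),
        ")>\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<naka_rushton: v_max %.2f mV, log10(K) %.3f, n %.3f, rss %.3g>\n",
    x$v_max, x$log10_K, x$n, x$rss))
  invisible(x)
}

#' @export
coef.naka_rushton <- function(object, ...) {
  c(v_max = object$v_max, log10_K = object$log10_K, n = object$n)
}

#' @export
predict.naka_rushton <- function(object, log10_intensity = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  if (is.null(log10_intensity))
    log10_intensity <- object$data$log10_intensity
  object$v_max /
    (1 + 10^(object$n * (object$log10_K - log10_intensity)))
}

#' @export
plot.naka_rushton <- function(x, ...) {
  graphics::plot(x$data$log10_intensity, x$data$response,
                 xlab = "log10 intensity (photons/cm2/s)",
                 ylab = "Response (mV)", ...)
  if (x$converged) {
    lI <- seq(min(x$data$log10_intensity), max(x$data$log10_intensity),
              length.out = 200)
    graphics::lines(lI, predict(x, lI))
    graphics::abline(v = x$log10_K, h = x$v_max / 2, lty = 3,
                     col = "grey50")
  }
  invisible(x)
}

#' Equivalent intensity for a response amplitude
#'
#' Inverts the fitted Naka-Rushton function:
#' \deqn{I_{eq} = K (V / (V_{max} - V))^{1/n}.}
#' Responses at or above `v_max` are clamped to `clamp * v_max` (flagged
#' via attribute `"clamped"`); non-positive responses give `NA`.
#'
#' @param fit A converged [fit_naka_rushton()] object.
#' @param response Response amplitude(s), mV.
#' @param clamp Clamping fraction for saturating responses (default 0.999).
#' @return Equivalent intensities (photons/cm^2/s) with attribute
#'   `"clamped"` (logical vector).
#' @export
equivalent_intensity <- function(fit, response, clamp = 0.999) {
  stopifnot(inherits(fit, "naka_rushton"))
  if (!fit$converged) stop("Naka-Rushton fit did not converge")
  clamped <- is.finite(response) & response >= fit$v_max
  v <- ifelse(clamped, clamp * fit$v_max, response)
  out <- ifelse(v > 0,
                10^fit$log10_K * (v / (fit$v_max - v))^(1 / fit$n),
                NA_real_)
  attr(out, "clamped") <- clamped
  out
}

#' Transform isoquantal responses into a spectral sensitivity curve
#'
#' Converts the mean response amplitude at each wavelength of an isoquantal
#' spectral series into sensitivity via the cell's V-log(I) Naka-Rushton
#' fit: each depolarizing response is mapped to the equivalent intensity
#' that would evoke it at the V-log(I) wavelength, and sensitivity is the
#' equivalent intensity relative to the isoquantal stimulus intensity,
#' peak-normalized. Because the transform linearizes the compressive
#' intensity-response relation, the result estimates the cell's underlying
#' absorbance spectrum up to a scale factor.
#'
#' Hyperpolarizing (negative) mean responses reflect opponent inhibition,
#' not opsin absorption: they are mapped to sensitivity 0 and recorded in
#' the `"hyperpolarizing"` attribute. Responses at or above `v_max` are
#' clamped (attribute `"clamped"`).
#'
#' @param responses Data.frame with columns `wavelength_nm` and
#'   `amplitude_mV` (repeat-mean signed amplitudes).
#' @param fit A converged [fit_naka_rushton()].
#' @param isoquantal_intensity Photon flux of the spectral series
#'   (default 1.5e15). Only sets the pre-normalization scale.
#' @return A [spectrum()] of kind `"sensitivity"` with attributes
#'   `hyperpolarizing` and `clamped` (logical, per wavelength).
#' @export
responses_to_sensitivity <- function(responses, fit,
                                     isoquantal_intensity = 1.5e15) {
  stopifnot(is.data.frame(responses),
            all(c("wavelength_nm", "amplitude_mV") %in% names(responses)))
  responses <- responses[order(responses$wavelength_nm), ]
  v <- responses$amplitude_mV
  hyper <- v < 0
  ieq <- equivalent_intensity(fit, pmax(v, 0))
  s <- ieq / isoquantal_intensity
  s[hyper | !is.finite(s)] <- 0
  if (max(s) <= 0) stop("no depolarizing responses: cannot form a sensitivity curve")
  out <- spectrum(responses$wavelength_nm, s / max(s), "sensitivity")
  attr(out, "hyperpolarizing") <- hyper
  attr(out, "clamped") <- attr(ieq, "clamped")
  out
}
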