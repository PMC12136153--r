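#' Rhodopsin alpha-band absorbance (closed form)
#'
#' The A1 visual-pigment alpha-band template of Govardovskii and colleagues:
#' with `x = lambda_max / lambda`,
#' \deqn{S(x) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' where A = 69.7, B = 28, b = 0.922, C = -14.9, c = 1.104, D = 0.674 and
#' \eqn{a = 0.8795 + 0.0459 \exp(-(\lambda_{max}-300)^2/11940)}.
#'
#' This is the raw scalar formula; no normalization or peak anchoring is
#' applied (the raw curve peaks within ~0.6 nm of `lambda_max` and its
#' maximum is within ~0.3% of 1). Use [rhodopsin_template()] for a
#' grid-evaluated, anchored, peak-normalized spectrum.
#'
#' @param wavelength Wavelength(s) in nm.
#' @param lambda_max Nominal peak absorbance wavelength in nm, in [300, 700].
#' @return Numeric vector of absorbances in (0, 1.01).
#' @export
rhodopsin_absorbance <- function(wavelength, lambda_max) {
  if (length(lambda_max) != 1L || is.na(lambda_max) ||
      lambda_max < 300 || lambda_max > 700)
    stop("lambda_max must be a single value in [300, 700] nm")
  x <- lambda_max / wavelength
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

# Wavelength offset between the raw template's continuous argmax and the
# nominal lambda_max (raw peak sits up to ~0.6 nm short of lambda_max at the
# short-wavelength end of the fitting range).
template_peak_shift <- function(lambda_max) {
  opt <- stats::optimize(function(l) -rhodopsin_absorbance(l, lambda_max),
                         c(lambda_max - 15, lambda_max + 15), tol = 1e-6)
  lambda_max - opt$minimum
}

# Anchored, peak-normalized template value at arbitrary wavelengths
# (scalar-safe; rhodopsin_template wraps this into a spectrum object)
template_value <- function(wavelength, lambda_max, anchor = TRUE,
                           normalize = TRUE) {
  shift <- if (anchor) template_peak_shift(lambda_max) else 0
  v <- rhodopsin_absorbance(wavelength - shift, lambda_max)
  if (normalize) {
    pk <- rhodopsin_absorbance(lambda_max - shift, lambda_max)
    v <- pmin(v / pk, 1)
  }
  v
}

#' Rhodopsin tuning template on a wavelength grid
#'
#' Evaluates the alpha-band absorbance template ([rhodopsin_absorbance()])
#' on a grid. Because lambda_max is operationally defined as the wavelength
#' of peak sensitivity, the curve is anchored so that its continuous maximum
#' falls exactly at `lambda_max` (a wavelength shift of at most ~0.6 nm
#' relative to the raw parameterization), then peak-normalized.
#'
#' No beta band is included: over the 310-630 nm measurement range used for
#' these cells the alpha band dominates.
#'
#' @param lambda_max Peak wavelength in nm, in [300, 700].
#' @param grid Evaluation grid in nm, within [250, 800]. Default 300-700 nm
#'   at 1 nm, the grid used for template fitting.
#' @param anchor Shift the curve so its peak is exactly at `lambda_max`
#'   (default `TRUE`).
#' @param normalize Scale so the maximum over `grid` is exactly 1
#'   (default `TRUE`).
#' @return A [spectrum()] of kind `"absorbance"`.
#' @examples
#' tpl <- rhodopsin_template(355)
#' peak_wavelength(tpl)
#' @export
rhodopsin_template <- function(lambda_max, grid = seq(300, 700, by = 1),
                               anchor = TRUE, normalize = TRUE) {
  grid <- as.numeric(grid)
  if (any(grid < 250) || any(grid > 800))
    stop("template grid must lie within [250, 800] nm")
  # normalization is against the continuous peak value so values on coarse
  # grids stay comparable across lambda_max
  v <- template_value(grid, lambda_max, anchor = anchor,
                      normalize = normalize)
  spectrum(grid, v, "absorbance")
}

#' Full width at half maximum of the rhodopsin template
#'
#' Computed on a 0.5 nm grid by linear interpolation of the half-maximum
#' crossings; used by the broadband-cell bandwidth rule.
#'
#' @param lambda_max Peak wavelength in nm.
#' @return FWHM in nm.
#' @export
template_fwhm <- function(lambda_max) {
  g <- seq(max(250, lambda_max - 200), min(800, lambda_max + 250), by = 0.5)
  tpl <- rhodopsin_template(lambda_max, g)
  halfmax_span(tpl$wavelength, tpl$value, level = 0.5)
}

# Total wavelength span where value >= level * max(value), with linear
# interpolation at the crossings. Shared by template_fwhm and the
# broadband classification rule.
halfmax_span <- function(wavelength, value, level = 0.5) {
  thr <- level * max(value)
  above <- value >= thr
  if (!any(above)) return(0)
  i1 <- which(above)[1]
  i2 <- max(which(above))
  lo <- wavelength[i1]
  if (i1 > 1) {
    f <- (thr - value[i1 - 1]) / (value[i1] - value[i1 - 1])
    lo <- wavelength[i1 - 1] + f * (wavelength[i1] - wavelength[i1 - 1])
  }
  hi <- wavelength[i2]
  if (i2 < length(wavelength)) {
    f <- (value[i2] - thr) / (value[i2] - value[i2 + 1])
    hi <- wavelength[i2] + f * (wavelength[i2 + 1] - wavelength[i2])
  }
  hi - lo
}
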