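#' Construct a spectrum
#'
#' A spectrum is a function of wavelength sampled on a strictly increasing
#' nanometre grid: a spectral sensitivity, an opsin absorbance curve, a wing
#' reflectance, a light-source emission, or a (possibly signed) normalized
#' response curve.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of the same length. Non-negative for
#'   sensitivity/absorbance/reflectance/emission spectra; `kind = "response"`
#'   spectra may be signed (hyperpolarizing responses are negative).
#' @param kind One of `"sensitivity"`, `"absorbance"`, `"reflectance"`,
#'   `"emission"`, `"response"`.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelength`, `value` and `kind`.
#' @examples
#' s <- spectrum(seq(300, 700, 10), rep(1, 41), "reflectance")
#' peak_wavelength(s)
#' @export
spectrum <- function(wavelength, value,
                     kind = c("sensitivity", "absorbance", "reflectance",
                              "emission", "response")) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have equal length")
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least two samples")
  if (anyNA(wavelength) || anyNA(value))
    stop("spectrum contains missing values")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (kind != "response" && any(value < 0))
    stop("negative values are only allowed for kind = 'response'")
  structure(list(wavelength = wavelength, value = value, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d samples, %g-%g nm>\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, value = x$value)
}

#' @export
plot.spectrum <- function(x, ..., xlab = "Wavelength (nm)", ylab = x$kind,
                          type = "l") {
  graphics::plot(x$wavelength, x$value, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Wavelength of the spectrum's maximum
#'
#' @param x A [spectrum()].
#' @return The grid wavelength at which `value` is largest.
#' @export
peak_wavelength <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  x$wavelength[which.max(x$value)]
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the target grid must lie within the span of the
#' source grid (no extrapolation).
#'
#' @param x A [spectrum()].
#' @param grid Numeric vector of target wavelengths (nm), strictly increasing.
#' @return A [spectrum()] of the same kind on `grid`.
#' @export
resample <- function(x, grid) {
  stopifnot(inherits(x, "spectrum"))
  grid <- as.numeric(grid)
  if (any(grid < min(x$wavelength)) || any(grid > max(x$wavelength)))
    stop("target grid extends beyond the source spectrum; refusing to extrapolate")
  v <- stats::approx(x$wavelength, x$value, xout = grid, method = "linear")$y
  spectrum(grid, v, x$kind)
}

#' Peak-normalize a spectrum
#'
#' Divides by the maximum value so the peak is exactly 1; ratios between
#' wavelengths (the shape) are unchanged. For signed response curves the
#' depolarizing (positive) peak is the reference.
#'
#' @param x A [spectrum()].
#' @return A [spectrum()] with `max(value) == 1`.
#' @export
normalize_peak <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  m <- max(x$value)
  if (m <= 0) stop("cannot peak-normalize: maximum value is not positive")
  out <- x
  out$value <- x$value / m
  out
}

#' Read / write two-column spectrum CSV files
#'
#' The on-disk format is a CSV with a one-line header
#' `wavelength_nm,value`.
#'
#' @param path File path.
#' @param kind Spectrum kind tag, see [spectrum()].
#' @return `read_spectrum` returns a [spectrum()]; `write_spectrum`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path, kind = "sensitivity") {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("expected columns wavelength_nm,value in ", path)
  spectrum(d$wavelength_nm, d$value, kind)
}

#' @param x A [spectrum()] (for `write_spectrum`).
#' @rdname read_spectrum
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
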