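#' Predicted photoreceptor excitation by a reflected stimulus
#'
#' Quantum-catch style linear model of how strongly a wing stimulus drives
#' a photoreceptor: the wavelength integral of reflectance times opsin
#' absorbance (times an optional illuminant),
#' \deqn{E = \int R(\lambda) S(\lambda) L(\lambda) d\lambda,}
#' evaluated by the trapezoidal rule on the common grid. No receptor-noise
#' color space is applied: the quantity of interest is the raw predicted
#' drive. With `L` omitted the illuminant is flat.
#'
#' @param reflectance A [spectrum()] of kind `"reflectance"`.
#' @param lambda_max Peak of the receptor's opsin template, nm.
#'   Alternatively pass a precomputed absorbance spectrum via `template`.
#' @param template Optional absorbance [spectrum()] overriding
#'   `lambda_max`.
#' @param illuminant Optional emission [spectrum()].
#' @return Excitation (unitless, grid-integral scale). Disjoint wavelength
#'   supports return 0 with a warning.
#' @examples
#' wht <- simulate_wing_reflectance("white")
#' yel <- simulate_wing_reflectance("yellow")
#' predicted_excitation(yel, 355) / predicted_excitation(wht, 355)
#' @export
predicted_excitation <- function(reflectance, lambda_max = NULL,
                                 template = NULL, illuminant = NULL) {
  stopifnot(inherits(reflectance, "spectrum"))
  if (is.null(template)) {
    if (is.null(lambda_max)) stop("give lambda_max or a template spectrum")
    grid <- reflectance$wavelength
    grid <- grid[grid >= 250 & grid <= 800]
    template <- rhodopsin_template(lambda_max, grid = grid)
  }
  lo <- max(min(reflectance$wavelength), min(template$wavelength))
  hi <- min(max(reflectance$wavelength), max(template$wavelength))
  if (!is.null(illuminant)) {
    lo <- max(lo, min(illuminant$wavelength))
    hi <- min(hi, max(illuminant$wavelength))
  }
  if (lo >= hi) {
    warning("spectra have disjoint wavelength supports; excitation is 0")
    return(0)
  }
  grid <- sort(unique(c(
    reflectance$wavelength[reflectance$wavelength >= lo &
                             reflectance$wavelength <= hi],
    template$wavelength[template$wavelength >= lo &
                          template$wavelength <= hi])))
  y <- resample(reflectance, grid)$value * resample(template, grid)$value
  if (!is.null(illuminant)) y <- y * resample(illuminant, grid)$value
  sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
}

#' Excitation of a receptor family by a set of wing colors
#'
#' Computes [predicted_excitation()] for every (lambda_max, color) pair.
#' Two normalizations are reported alongside the raw integral:
#' `excitation_rel` divides by the template's own area (the
#' reflectance-weighted mean absorbance), which removes the trivial growth
#' of the raw integral with the template's bandwidth and is the right
#' scale for comparing how strongly the *same* stimulus drives receptors
#' of *different* tuning; `excitation_norm` scales within each lambda_max
#' so the most exciting color is 1, the contrast a single receptor sees
#' between stimuli.
#'
#' @param colors Named list of reflectance [spectrum()] objects.
#' @param lambda_max_range Numeric vector of template peaks, nm.
#' @param illuminant Optional emission [spectrum()].
#' @return Data.frame: `lambda_max_nm`, `color`, `excitation` (raw
#'   integral), `excitation_rel` (area-normalized), `excitation_norm`
#'   (max over colors = 1 per lambda_max).
#' @export
excitation_sweep <- function(colors, lambda_max_range,
                             illuminant = NULL) {
  stopifnot(length(names(colors)) == length(colors))
  flat <- spectrum(colors[[1]]$wavelength,
                   rep(1, length(colors[[1]]$wavelength)), "reflectance")
  rows <- list()
  for (lm in lambda_max_range) {
    e <- vapply(colors, predicted_excitation, numeric(1),
                lambda_max = lm, illuminant = illuminant)
    area <- predicted_excitation(flat, lm, illuminant = illuminant)
    rows[[length(rows) + 1L]] <-
      data.frame(lambda_max_nm = lm, color = names(colors),
                 excitation = unname(e),
                 excitation_rel = unname(e) / area,
                 excitation_norm = unname(e) / max(e))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
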