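#' Estimate the wavelength of peak sensitivity by template fitting
#'
#' Fits the rhodopsin tuning template to a measured spectral sensitivity
#' curve: lambda_max minimizes the sum of squared deviations between the
#' peak-normalized sensitivity and the peak-normalized template, evaluated
#' at the measurement wavelengths. A 1 nm grid scan over the search range
#' brackets the optimum (ties broken toward the smallest lambda_max),
#' followed by continuous refinement with [stats::optimize()].
#'
#' Wavelength bins with non-positive sensitivity, and bins flagged as
#' hyperpolarizing by [responses_to_sensitivity()], are excluded: they
#' carry opponent inhibition, not opsin absorption.
#'
#' @param sens A [spectrum()] of measured sensitivity (any kind; values on
#'   the normalized scale).
#' @param search Search range for lambda_max, nm (default c(330, 650)).
#' @param r2_floor Fits with r2 below this are flagged unreliable
#'   (default 0.5).
#' @return An object of class `"template_fit"`: `lambda_max`, `r2`,
#'   `residuals` (per included wavelength), `wavelengths` (included),
#'   `n_excluded`, `reliable`.
#' @examples
#' s <- rhodopsin_template(355, grid = seq(310, 630, 10))
#' fit_lambda_max(s)$lambda_max
#' @export
fit_lambda_max <- function(sens, search = c(330, 650), r2_floor = 0.5) {
  stopifnot(inherits(sens, "spectrum"), length(search) == 2L,
            search[1] < search[2])
  hyper <- attr(sens, "hyperpolarizing")
  keep <- sens$value > 0
  if (!is.null(hyper)) keep <- keep & !hyper
  if (sum(keep) < 3L) stop("fewer than 3 usable wavelengths for template fitting")
  w <- sens$wavelength[keep]
  y <- sens$value[keep] / max(sens$value[keep])
  sse <- function(lm) sum((y - template_value(w, lm))^2)
  grid <- seq(search[1], search[2], by = 1)
  scan <- vapply(grid, sse, numeric(1))
  best <- grid[which.min(scan)]  # which.min takes the smallest on ties
  lo <- max(search[1], best - 1)
  hi <- min(search[2], best + 1)
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-4)
  lambda_max <- opt$minimum
  if (sse(best) < opt$objective) {  # guard: refinement must not be worse
    lambda_max <- best
    opt$objective <- sse(best)
  }
  res <- y - template_value(w, lambda_max)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - opt$objective / ss_tot else NA_real_
  structure(list(lambda_max = lambda_max, r2 = r2, residuals = res,
                 wavelengths = w, fitted = template_value(w, lambda_max),
                 observed = y, n_excluded = sum(!keep),
                 reliable = is.finite(r2) && r2 >= r2_floor,
                 search = search),
            class = "template_fit")
}

#' @export
print.template_fit <- function(x, ...) {
  cat(sprintf("<template_fit: lambda_max %.1f nm, r2 %.3f%s>\n",
              x$lambda_max, x$r2,
              if (x$reliable) "" else ", UNRELIABLE"))
  invisible(x)
}

#' @export
coef.template_fit <- function(object, ...) {
  c(lambda_max = object$lambda_max)
}

#' @export
plot.template_fit <- function(x, ...) {
  graphics::plot(x$wavelengths, x$observed, xlab = "Wavelength (nm)",
                 ylab = "Normalized sensitivity", ...)
  g <- seq(min(x$wavelengths), max(x$wavelengths), by = 1)
  graphics::lines(g, template_value(g, x$lambda_max))
  graphics::abline(v = x$lambda_max, lty = 3, col = "grey50")
  invisible(x)
}

#' Count modes of a distribution of lambda_max estimates
#'
#' Simple unimodality diagnostic: the number of local maxima of a Gaussian
#' kernel density estimate at a given bandwidth. A homogeneous population
#' of cells (one opsin complement, continuous expression-ratio tuning)
#' should give a single mode; two discrete opsin pools would give two.
#'
#' @param x Numeric vector (e.g. fitted lambda_max values, nm).
#' @param bw Kernel bandwidth in the units of `x` (default 5 nm).
#' @return Integer number of density modes.
#' @export
count_modes <- function(x, bw = 5) {
  d <- stats::density(x, bw = bw)
  y <- d$y
  sum(diff(sign(diff(y))) == -2L) + (y[1] > y[2]) +
    (y[length(y)] > y[length(y) - 1])
}
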