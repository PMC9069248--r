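#' Pseudo-Voigt profile
#'
#' Linear mix of a Lorentzian and a Gaussian of common FWHM, unit height
#' at the centre: `eta * L + (1 - eta) * G`.
#'
#' @param x abscissa
#' @param centre peak centre
#' @param fwhm full width at half maximum (> 0)
#' @param eta Lorentzian fraction in `[0, 1]`
#' @return profile values (unit peak height)
#' @export
pseudo_voigt <- function(x, centre, fwhm, eta) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  u <- (x - centre) / (fwhm / 2)
  eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2)
}

#' @rdname pseudo_voigt
#' @description `pseudo_voigt_area()` is the analytic area of a
#'   unit-height pseudo-Voigt times `amplitude`.
#' @param amplitude peak height
#' @export
pseudo_voigt_area <- function(amplitude, fwhm, eta) {
  amplitude * fwhm * (eta * pi / 2 + (1 - eta) * 0.5 * sqrt(pi / log(2)))
}

#' Split pseudo-Voigt profile
#'
#' Independent FWHM and mixing fraction on each side of the centre; used
#' for asymmetric Bragg maxima.
#'
#' @inheritParams pseudo_voigt
#' @param fwhm_left,fwhm_right side widths (each the FWHM the side would
#'   have if mirrored)
#' @param eta_left,eta_right side mixing fractions
#' @export
split_pseudo_voigt <- function(x, centre, fwhm_left, fwhm_right,
                               eta_left, eta_right) {
  left <- x < centre
  out <- numeric(length(x))
  out[left] <- pseudo_voigt(x[left], centre, fwhm_left, eta_left)
  out[!left] <- pseudo_voigt(x[!left], centre, fwhm_right, eta_right)
  out
}

#' Fit a split pseudo-Voigt to one powder-diffraction maximum
#'
#' Least-squares fit of a split pseudo-Voigt plus a linear background over
#' a two-theta window containing one dominant peak.  The effective breadth
#' used downstream by Scherrer analysis is the mean of the two side
#' widths.
#'
#' @param pattern data.frame with columns `tth` (two-theta degrees) and
#'   `intensity`
#' @param window length-2 numeric: two-theta range to fit
#' @return object of class `peak_fit`: `centre`, `fwhm_left`,
#'   `fwhm_right`, `fwhm` (mean), `eta_left`, `eta_right`, `amplitude`,
#'   `bg_intercept`, `bg_slope`, `rss`, `converged`
#' @export
fit_split_pseudo_voigt <- function(pattern, window) {
  stopifnot(all(c("tth", "intensity") %in% names(pattern)), length(window) == 2)
  window <- sort(window)
  sel <- pattern$tth >= window[1] & pattern$tth <= window[2]
  if (sum(sel) < 15) stop("need at least 15 points in the fit window")
  x <- pattern$tth[sel]; y <- pattern$intensity[sel]

  bg0 <- min(y)
  amp0 <- max(y) - bg0
  c0 <- x[which.max(y)]
  half <- y >= bg0 + amp0 / 2
  w0 <- max(diff(range(x[half])), 4 * mean(diff(x)))

  model <- function(p) {
    p["amp"] * split_pseudo_voigt(x, p["centre"], p["fwl"], p["fwr"],
                                  p["etal"], p["etar"]) +
      p["b0"] + p["b1"] * (x - mean(x))
  }
  start <- c(centre = c0, fwl = w0, fwr = w0, etal = 0.5, etar = 0.5,
             amp = amp0, b0 = bg0, b1 = 0)
  lower <- c(window[1], 1e-4, 1e-4, 0, 0, 0, -Inf, -Inf)
  upper <- c(window[2], diff(window), diff(window), 1, 1, Inf, Inf, Inf)
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!(fit$info %in% 1:4))
    stop("peak fit did not converge (last residual sum ", signif(fit$deviance, 4), ")")
  p <- fit$par
  edge <- min(p[["centre"]] - window[1], window[2] - p[["centre"]])
  if (edge < (p[["fwl"]] + p[["fwr"]]) / 2)
    warning("fitted peak centre is within one breadth of the window edge")
  structure(list(centre = p[["centre"]],
                 fwhm_left = p[["fwl"]], fwhm_right = p[["fwr"]],
                 fwhm = (p[["fwl"]] + p[["fwr"]]) / 2,
                 eta_left = p[["etal"]], eta_right = p[["etar"]],
                 amplitude = p[["amp"]],
                 bg_intercept = p[["b0"]], bg_slope = p[["b1"]],
                 rss = fit$deviance, converged = TRUE),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("peak: centre %.4f deg, fwhm %.4f deg (L %.4f / R %.4f), eta %.2f/%.2f\n",
              x$centre, x$fwhm, x$fwhm_left, x$fwhm_right, x$eta_left, x$eta_right))
  invisible(x)
}

#' Scherrer coherence length
#'
#' `CL = K * lambda / (beta * cos(theta))` with the breadth `beta` taken
#' as the FWHM in radians (no integral-breadth or instrumental
#' correction unless supplied via `beta_instrument`).
#'
#' @param beta peak breadth FWHM, radians
#' @param theta Bragg angle (half the two-theta of the maximum), radians
#' @param K Scherrer shape constant (default 0.9)
#' @param lambda wavelength, angstrom (default Cu K-alpha 1.5406)
#' @param beta_instrument optional instrumental breadth, radians,
#'   subtracted in quadrature
#' @return coherence length, angstrom
#' @export
#' @examples
#' scherrer_cl(0.01, 12.86 * pi / 180)   # about 142 A
scherrer_cl <- function(beta, theta, K = 0.9, lambda = 1.5406,
                        beta_instrument = 0) {
  if (beta <= 0) stop("beta must be positive")
  if (beta >= pi / 8) stop("beta above pi/8 rad is not a sane peak breadth")
  if (any(c(K, lambda) <= 0) || theta <= 0) stop("K, lambda, theta must be positive")
  if (beta_instrument > 0) {
    if (beta_instrument >= beta) stop("instrumental breadth exceeds observed breadth")
    beta <- sqrt(beta^2 - beta_instrument^2)
  }
  K * lambda / (beta * cos(theta))
}

#' Coherence length from a pattern window
#'
#' Fits the peak with [fit_split_pseudo_voigt()] and converts the mean
#' FWHM to a Scherrer coherence length.
#'
#' @inheritParams fit_split_pseudo_voigt
#' @inheritParams scherrer_cl
#' @return list with the `peak_fit` and `cl` (angstrom)
#' @export
coherence_length <- function(pattern, window, K = 0.9, lambda = 1.5406,
                             beta_instrument = 0) {
  pk <- fit_split_pseudo_voigt(pattern, window)
  beta <- pk$fwhm * pi / 180
  theta <- pk$centre / 2 * pi / 180
  list(peak = pk,
       cl = scherrer_cl(beta, theta, K = K, lambda = lambda,
                        beta_instrument = beta_instrument))
}
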