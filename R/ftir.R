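#' FT-IR spectrum container
#'
#' @param wavenumber strictly monotone grid, 1/cm (ascending or
#'   descending)
#' @param absorbance absorbance values
#' @return object of class `ir_spectrum` (stored ascending)
#' @export
ir_spectrum <- function(wavenumber, absorbance) {
  stopifnot(is.numeric(wavenumber), is.numeric(absorbance),
            length(wavenumber) == length(absorbance), length(wavenumber) >= 3)
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0))) stop("wavenumber grid must be strictly monotone")
  if (d[1] < 0) {
    wavenumber <- rev(wavenumber); absorbance <- rev(absorbance)
  }
  structure(list(wavenumber = wavenumber, absorbance = absorbance),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("IR spectrum: %d points, %.0f..%.0f 1/cm\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Window a spectrum and subtract a linear baseline
#'
#' Restricts the spectrum to `[lo, hi]` 1/cm and subtracts the straight
#' line anchored at the window endpoints.  Each anchor is the mean of the
#' `anchor_points` outermost points of the window, which keeps the
#' correction exact for a linear background while making it robust to
#' point noise at the endpoints.  Negative residual absorbance is kept
#' (no clipping).
#'
#' @param spectrum an [ir_spectrum()]
#' @param lo,hi window limits, 1/cm (any order)
#' @param anchor_points number of points averaged into each endpoint
#'   anchor (clipped to at most a third of the window)
#' @return baseline-corrected [ir_spectrum()] spanning the window
#' @export
baseline_and_window <- function(spectrum, lo, hi, anchor_points = 5) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  w <- sort(c(lo, hi))
  if (w[1] < min(spectrum$wavenumber) || w[2] > max(spectrum$wavenumber))
    stop("window outside the spectrum grid")
  sel <- spectrum$wavenumber >= w[1] & spectrum$wavenumber <= w[2]
  if (sum(sel) < 3) stop("window contains fewer than 3 points")
  x <- spectrum$wavenumber[sel]; y <- spectrum$absorbance[sel]
  n <- length(x)
  k <- max(1, min(anchor_points, floor(n / 3)))
  xl <- mean(x[seq_len(k)]); yl <- mean(y[seq_len(k)])
  xr <- mean(x[seq(n - k + 1, n)]); yr <- mean(y[seq(n - k + 1, n)])
  slope <- (yr - yl) / (xr - xl)
  ir_spectrum(x, y - (yl + slope * (x - xl)))
}

#' Fit the three-component nu2-carbonate band
#'
#' Least-squares fit of three pseudo-Voigt components with fixed centres
#' (defaults 878, 873, 866 1/cm: the A-type, B-type and labile carbonate
#' environments) to a baseline-corrected nu2 window.  Amplitudes, widths
#' and mixing fractions are free; component areas are analytic.
#'
#' @param corrected baseline-corrected [ir_spectrum()] windowed to the
#'   nu2 region (see [baseline_and_window()])
#' @param centres three fixed component centres, 1/cm
#' @return object of class `carbonate_fit`: data.frame `components`
#'   (centre, amplitude, fwhm, eta, area), `area_total`, `rss`
#' @export
fit_carbonate_triplet <- function(corrected, centres = c(878, 873, 866)) {
  stopifnot(inherits(corrected, "ir_spectrum"))
  if (length(centres) != 3) stop("centres must have length 3")
  x <- corrected$wavenumber; y <- corrected$absorbance
  step <- mean(diff(x))

  if (all(abs(y) < 1e-14)) {
    comps <- data.frame(centre = centres, amplitude = 0, fwhm = NA_real_,
                        eta = NA_real_, area = 0)
    return(structure(list(components = comps, area_total = 0, rss = 0),
                     class = "carbonate_fit"))
  }

  amp0 <- vapply(centres, function(cc) max(y[which.min(abs(x - cc))], 1e-6),
                 numeric(1))
  lower <- c(0, 0, 0, step / 2, step / 2, step / 2, 0, 0, 0)
  upper <- c(Inf, Inf, Inf, 60, 60, 60, 1, 1, 1)
  model <- function(p) {
    p[1] * pseudo_voigt(x, centres[1], p[4], p[7]) +
    p[2] * pseudo_voigt(x, centres[2], p[5], p[8]) +
    p[3] * pseudo_voigt(x, centres[3], p[6], p[9])
  }
  # the heavily overlapped sub-bands make the least-squares surface
  # multimodal; run from a narrow and a broad width start and keep the
  # better optimum
  fit <- NULL
  for (w0 in c(4, 8)) {
    start <- c(a1 = amp0[1], a2 = amp0[2], a3 = amp0[3],
               w1 = w0, w2 = w0, w3 = w0, e1 = 0.5, e2 = 0.5, e3 = 0.5)
    cand <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                               fn = function(p) y - model(p),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 1000, ftol = 1e-14, ptol = 1e-14))
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
  }
  if (!(fit$info %in% 1:4))
    stop("carbonate triplet fit did not converge (rss ", signif(fit$deviance, 4), ")")
  p <- fit$par
  fw <- p[4:6]
  if (any(fw < step))
    warning("fitted component width below the grid spacing")
  comps <- data.frame(centre = centres, amplitude = p[1:3], fwhm = fw,
                      eta = p[7:9],
                      area = pseudo_voigt_area(p[1:3], fw, p[7:9]))
  structure(list(components = comps, area_total = sum(comps$area),
                 rss = fit$deviance), class = "carbonate_fit")
}

#' @export
print.carbonate_fit <- function(x, ...) {
  cat(sprintf("nu2 carbonate fit: total area %.5g\n", x$area_total))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Net phosphate band area
#'
#' Trapezoidal net area of the nu1/nu3 phosphate envelope after an
#' endpoint-anchored linear baseline over the integration window
#' (default 1200-900 1/cm).
#'
#' @param spectrum an [ir_spectrum()] covering the window
#' @param lo,hi integration limits, 1/cm
#' @export
phosphate_area <- function(spectrum, lo = 900, hi = 1200) {
  bw <- baseline_and_window(spectrum, lo, hi)
  trapz_area(bw$wavenumber, bw$absorbance)
}

#' Carbonate-to-phosphate area ratio of one spectrum
#'
#' Full single-spectrum pipeline: nu2 window 910-840 1/cm with linear
#' baseline, fixed-centre triplet fit, phosphate net area, and the
#' nu2CO3 : nu1nu3PO4 area ratio.
#'
#' @param spectrum an [ir_spectrum()] covering at least 1200-840 1/cm
#' @param centres triplet centres passed to [fit_carbonate_triplet()]
#' @param nu2_window,po4_window integration windows, 1/cm
#' @return list: `fit` (the `carbonate_fit`), `co3_area`, `po4_area`,
#'   `ratio`
#' @export
carbonate_ratio <- function(spectrum, centres = c(878, 873, 866),
                            nu2_window = c(840, 910),
                            po4_window = c(900, 1200)) {
  corrected <- baseline_and_window(spectrum, nu2_window[1], nu2_window[2])
  fit <- fit_carbonate_triplet(corrected, centres)
  po4 <- phosphate_area(spectrum, po4_window[1], po4_window[2])
  if (po4 <= 0) stop("non-positive phosphate band area")
  list(fit = fit, co3_area = fit$area_total, po4_area = po4,
       ratio = fit$area_total / po4)
}

#' Carbonate calibration curve and prediction
#'
#' Ordinary least squares of known wt% CO3 on the nu2CO3 : nu1nu3PO4 area
#' ratio across calibration standards; prediction for an unknown spectrum
#' is the line evaluated at its ratio, floored at 0 wt%.
#'
#' @param standards list of `list(spectrum = <ir_spectrum>, wtpc =
#'   <known wt%>)`, at least 3
#' @param ... options passed to [carbonate_ratio()]
#' @return object of class `carbonate_calibration`: `slope`, `intercept`,
#'   `r2`, `n`, `ratios`, `wtpc`
#' @export
carbonate_calibration <- function(standards, ...) {
  if (length(standards) < 3) stop("need at least 3 calibration standards")
  ratios <- vapply(standards, function(s) carbonate_ratio(s$spectrum, ...)$ratio,
                   numeric(1))
  wtpc <- vapply(standards, function(s) s$wtpc, numeric(1))
  if (var(ratios) < 1e-20) stop("calibration standards have identical ratios")
  fit <- lm(wtpc ~ ratios)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r2 = summary(fit)$r.squared, n = length(ratios),
                 ratios = ratios, wtpc = wtpc),
            class = "carbonate_calibration")
}

#' @rdname carbonate_calibration
#' @param calibration a `carbonate_calibration`
#' @param unknown an [ir_spectrum()] to predict
#' @return predicted carbonate content, wt% (>= 0)
#' @export
predict_carbonate <- function(calibration, unknown, ...) {
  stopifnot(inherits(calibration, "carbonate_calibration"))
  r <- carbonate_ratio(unknown, ...)$ratio
  max(0, calibration$intercept + calibration$slope * r)
}

#' @export
print.carbonate_calibration <- function(x, ...) {
  cat(sprintf("carbonate calibration: wt%% = %.4g + %.4g * ratio (R^2 %.4f, n = %d)\n",
              x$intercept, x$slope, x$r2, x$n))
  invisible(x)
}
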