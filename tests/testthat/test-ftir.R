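test_that("a straight-line spectrum vanishes after baseline correction", {
  x <- seq(800, 1000, by = 2)
  sp <- ir_spectrum(x, 0.3 + 0.001 * x)
  out <- baseline_and_window(sp, 840, 910)
  expect_equal(range(out$wavenumber), c(840, 910))
  expect_lt(max(abs(out$absorbance)), 1e-12)
})

test_that("a band on a sloped baseline keeps its area after correction", {
  x <- seq(700, 1100, by = 1)
  fwhm <- 8; eta <- 0.1; amp <- 0.8
  sp <- ir_spectrum(x, amp * pseudo_voigt(x, 873, fwhm, eta) +
                       0.05 + 2e-4 * (x - 700))
  out <- baseline_and_window(sp, 780, 970)
  got <- sum(diff(out$wavenumber) *
             (out$absorbance[-1] + out$absorbance[-length(out$absorbance)]) / 2)
  expect_lt(abs(got - pseudo_voigt_area(amp, fwhm, eta)) /
            pseudo_voigt_area(amp, fwhm, eta), 0.01)
})

test_that("windows outside the grid and descending grids are handled", {
  x <- seq(1000, 800, by = -2)   # descending input
  sp <- ir_spectrum(x, rep(0.1, length(x)))
  expect_error(baseline_and_window(sp, 700, 900), "outside")
  out <- baseline_and_window(sp, 840, 910)
  expect_true(all(diff(out$wavenumber) > 0))
})

test_that("the fixed-centre triplet recovers known component areas", {
  x <- seq(840, 910, by = 0.5)
  areas <- c(1.0, 2.0, 0.5)
  fwhm <- c(6, 7, 5.5); eta <- c(0.5, 0.5, 0.5)
  amp <- areas / pseudo_voigt_area(1, fwhm, eta)
  y <- amp[1] * pseudo_voigt(x, 878, fwhm[1], eta[1]) +
       amp[2] * pseudo_voigt(x, 873, fwhm[2], eta[2]) +
       amp[3] * pseudo_voigt(x, 866, fwhm[3], eta[3])
  fit <- fit_carbonate_triplet(ir_spectrum(x, y))
  expect_equal(fit$components$area, areas, tolerance = 0.02)
  # area additivity
  expect_equal(fit$area_total, sum(fit$components$area), tolerance = 1e-8)
})

test_that("degenerate triplet inputs are handled explicitly", {
  x <- seq(840, 910, by = 1)
  zero <- fit_carbonate_triplet(ir_spectrum(x, numeric(length(x))))
  expect_equal(zero$area_total, 0)
  expect_error(fit_carbonate_triplet(ir_spectrum(x, rep(1, length(x))),
                                     centres = c(878, 873)), "length 3")
})

test_that("perfectly linear standards calibrate exactly", {
  stds <- lapply(c(2, 4, 6, 8), function(w)
    list(spectrum = make_ir_spectrum(w), wtpc = w))
  cal <- carbonate_calibration(stds)
  expect_lt(abs(cal$intercept), 1e-4)
  unknown <- make_ir_spectrum(5)
  expect_lt(abs(predict_carbonate(cal, unknown) - 5), 1e-4)
  expect_error(carbonate_calibration(stds[1:2]), "at least 3")
})

test_that("the ratio cancels a uniform absorbance scale", {
  sp <- make_ir_spectrum(4.4)
  r1 <- carbonate_ratio(sp)$ratio
  sp2 <- ir_spectrum(sp$wavenumber, 3.7 * sp$absorbance)
  expect_equal(carbonate_ratio(sp2)$ratio, r1, tolerance = 1e-6)
})

test_that("a carbonate-free unknown is floored at zero", {
  stds <- lapply(c(2, 5, 8), function(w)
    list(spectrum = make_ir_spectrum(w), wtpc = w))
  cal <- carbonate_calibration(stds)
  cal$intercept <- -1   # force a negative raw prediction
  expect_gte(suppressWarnings(predict_carbonate(cal, make_ir_spectrum(0))), 0)
})

test_that("predictions are monotone across a noisy concentration ladder", {
  stds <- lapply(c(1.5, 3.5, 5.5, 7.5), function(w)
    list(spectrum = make_ir_spectrum(w, noise = 0.01, seed = round(w * 10)),
         wtpc = w))
  cal <- carbonate_calibration(stds)
  ladder <- c(2, 4, 6, 8)
  preds <- vapply(ladder, function(w)
    predict_carbonate(cal, make_ir_spectrum(w, noise = 0.01,
                                            seed = 1000 + round(w))),
    numeric(1))
  expect_true(all(diff(preds) > 0))
})
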