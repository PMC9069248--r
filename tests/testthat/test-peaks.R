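make_pattern <- function(centre = 25.9, fwl = 0.2, fwr = 0.2, etal = 0.5,
                         etar = 0.5, amp = 100, bg0 = 10, bg1 = 0,
                         window = c(24.4, 27.4), step = 0.01, noise = 0,
                         seed = 1) {
  x <- seq(window[1], window[2], by = step)
  y <- amp * split_pseudo_voigt(x, centre, fwl, fwr, etal, etar) +
    bg0 + bg1 * (x - mean(x))
  if (noise > 0) { set.seed(seed); y <- y + rnorm(length(y), 0, noise * amp) }
  data.frame(tth = x, intensity = y)
}

test_that("a symmetric pseudo-Voigt peak round-trips through the fit", {
  p <- make_pattern(fwl = 0.2, fwr = 0.2, etal = 0.5, etar = 0.5)
  fit <- fit_split_pseudo_voigt(p, c(24.4, 27.4))
  expect_lt(abs(fit$centre - 25.9), 0.001)
  expect_lt(abs(fit$fwhm - 0.2) / 0.2, 0.01)
  expect_lt(abs(fit$eta_left - 0.5), 0.05)
})

test_that("a pure Gaussian profile drives the mixing fractions to zero", {
  p <- make_pattern(etal = 0, etar = 0)
  fit <- fit_split_pseudo_voigt(p, c(24.4, 27.4))
  expect_lt(fit$eta_left, 0.01)
  expect_lt(fit$eta_right, 0.01)
})

test_that("asymmetric side widths are recovered independently", {
  p <- make_pattern(fwl = 0.15, fwr = 0.30)
  fit <- fit_split_pseudo_voigt(p, c(24.4, 27.4))
  expect_lt(abs(fit$fwhm_left - 0.15) / 0.15, 0.02)
  expect_lt(abs(fit$fwhm_right - 0.30) / 0.30, 0.02)
})

test_that("too-narrow windows are rejected", {
  p <- make_pattern()
  expect_error(fit_split_pseudo_voigt(p, c(25.89, 25.95)), "15 points")
})

test_that("Scherrer equation reproduces closed-form arithmetic", {
  cl <- scherrer_cl(beta = 0.01, theta = 12.86 * pi / 180, K = 0.9,
                    lambda = 1.5406)
  expect_equal(cl, 0.9 * 1.5406 / (0.01 * cos(12.86 * pi / 180)),
               tolerance = 1e-12)
  expect_equal(cl, 142.2, tolerance = 0.001)
  # inverse proportionality and lambda-beta homogeneity
  expect_equal(scherrer_cl(0.02, 0.3), scherrer_cl(0.01, 0.3) / 2,
               tolerance = 1e-12)
  expect_equal(scherrer_cl(0.01 * 3, 0.3, lambda = 1.5406 * 3),
               scherrer_cl(0.01, 0.3), tolerance = 1e-12)
  expect_error(scherrer_cl(-0.01, 0.3), "beta")
  expect_error(scherrer_cl(0.5, 0.3), "beta")
})

test_that("the full fit-plus-Scherrer pipeline round-trips a known size", {
  cl_true <- 200
  theta <- 25.87 / 2 * pi / 180
  beta_deg <- 0.9 * 1.5406 / (cl_true * cos(theta)) * 180 / pi
  p <- make_pattern(centre = 25.87, fwl = beta_deg, fwr = beta_deg,
                    etal = 0.4, etar = 0.4, window = c(24.0, 27.8))
  res <- coherence_length(p, c(24.0, 27.8))
  expect_lt(abs(res$cl - cl_true), 2)
})

test_that("fitted breadth error shrinks as the window widens", {
  beta <- 0.25
  p <- make_pattern(centre = 25.9, fwl = beta, fwr = beta, etal = 0.6,
                    etar = 0.6, window = c(23.9, 27.9))
  errs <- vapply(c(0.45, 0.9, 1.9), function(half) {
    fit <- fit_split_pseudo_voigt(p, c(25.9 - half, 25.9 + half))
    abs(fit$fwhm - beta)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("sheet thickness and 002 coherence length correlate on joint synthetics", {
  # Bragg coherence lengths of platy nanocrystals run near tenfold the
  # real-space sheet thickness
  ts <- seq(18, 45, length.out = 10)
  cls <- vapply(ts, function(t) {
    pat <- make_peak_pattern(cl002 = 10 * t, cl030 = 25 * t, noise = 0.005,
                             seed = round(t * 7))
    coherence_length(pat, attr(pat, "window_002"))$cl
  }, numeric(1))
  expect_gt(cor(ts, cls), 0.9)
})
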