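# fast silicon-based fixtures: a 1-50 A grid matches the analysis range
# but the cheap 8-atom cell keeps each model evaluation around 40 ms
si_grid <- pdf_grid_range(1, 50, 0.05)
si_model <- si_pdf_model(si_grid)
si_truth_pdf <- function() {
  make_pdf_sample(si_parameter_set(), si_grid, model = si_model)$pdf
}

test_that("refinement started at the truth is a fixed point", {
  obs <- si_truth_pdf()
  params <- refine_only(si_parameter_set(), c("scale", "a"))
  res <- refine(obs, params, si_model)
  expect_lt(res$rw, 1e-10)
  expect_equal(param_values(res$params)[["a"]], 5.4312, tolerance = 1e-9)
  expect_equal(param_values(res$params)[["scale"]], 1, tolerance = 1e-9)
  expect_lte(res$rw, res$rw_initial)
})

test_that("a perturbed lattice parameter returns to the truth on noise-free data", {
  obs <- si_truth_pdf()
  start <- set_param(si_parameter_set(), "a", value = 5.4312 * 1.005)
  start <- set_param(start, "scale", value = 0.9)
  start <- refine_only(start, c("scale", "a"))
  res <- refine(obs, start, si_model)
  expect_true(res$converged)
  expect_lt(abs(param_values(res$params)[["a"]] - 5.4312), 1e-3)
  expect_lt(res$rw, 1e-6)
})

test_that("rw is invariant under a common scale of both curves", {
  obs <- si_truth_pdf()
  calc <- si_model(param_values(set_param(si_parameter_set(), "a",
                                          value = 5.46)))
  r1 <- rw_residual(obs, calc)
  obs2 <- pdf_grid(obs$r, 7.3 * obs$g)
  calc2 <- pdf_grid(calc$r, 7.3 * calc$g)
  expect_equal(rw_residual(obs2, calc2), r1, tolerance = 1e-12)
})

test_that("staged and joint refinement meet at the same optimum when well-posed", {
  obs <- si_truth_pdf()
  start <- set_param(si_parameter_set(), "a", value = 5.445)
  start <- set_param(start, "scale", value = 1.2)
  start <- refine_only(start, c("scale", "a"))
  joint <- refine(obs, start, si_model)
  staged <- staged_refine(obs, start, si_model,
                          stages = list("scale", "a", c("scale", "a")))
  expect_equal(param_values(staged$params)[["a"]],
               param_values(joint$params)[["a"]], tolerance = 1e-6)
  expect_equal(param_values(staged$params)[["scale"]],
               param_values(joint$params)[["scale"]], tolerance = 1e-6)
})

test_that("a single stage holding every refined parameter degenerates to refine", {
  obs <- si_truth_pdf()
  start <- set_param(si_parameter_set(), "a", value = 5.45)
  start <- refine_only(start, c("scale", "a"))
  joint <- refine(obs, start, si_model)
  one <- staged_refine(obs, start, si_model, stages = list(c("scale", "a")))
  expect_equal(param_values(one$params), param_values(joint$params),
               tolerance = 1e-10)
})

test_that("configuration errors are caught before any computation", {
  obs <- si_truth_pdf()
  params <- refine_only(si_parameter_set(), "a")
  expect_error(staged_refine(obs, params, si_model,
                             stages = list("a", "no_such_parameter")),
               "unknown parameter")
  expect_error(refine(obs, refine_only(si_parameter_set(), character(0)),
                      si_model),
               "at least one parameter")
  expect_error(refine_only(si_parameter_set(), "bogus"), "unknown parameter")
})

test_that("lattice recovery stays unbiased under a mis-set scale", {
  obs <- si_truth_pdf()
  start <- set_param(si_parameter_set(), "scale", value = 0.9)   # wrong, fixed
  start <- set_param(start, "a", value = 5.4312 * 1.004)
  start <- refine_only(start, "a")
  res <- refine(obs, start, si_model)
  expect_lt(abs(param_values(res$params)[["a"]] - 5.4312), 0.005)
})

test_that("apatite parameters are recovered across random truths at 1% noise", {
  # scaled-down recovery sweep: 6 seeded truth draws over the physical
  # ranges, short 1-25 A window and 0.1 A step for speed
  grid <- pdf_grid_range(1, 25, 0.1)
  model <- ha_pdf_model(grid)
  set.seed(29)
  err_a <- err_c <- err_occ <- err_t <- numeric(0)
  for (i in 1:6) {
    a_true <- runif(1, 9.40, 9.47); c_true <- runif(1, 6.87, 6.92)
    occ_true <- runif(1, 0.85, 1.0); t_true <- runif(1, 20, 40)
    truth <- ha_parameter_set(t = t_true)
    truth <- set_param(truth, "a", value = a_true)
    truth <- set_param(truth, "c", value = c_true)
    for (nm in c("occ_P", "occ_O1", "occ_O2", "occ_O3"))
      truth <- set_param(truth, nm, value = occ_true)
    obs <- make_pdf_sample(truth, grid, noise = 0.01,
                           seed = sample.int(1e6, 1), model = model)$pdf
    start <- ha_parameter_set(t = 30)
    start <- set_param(start, "a", value = 9.43)
    start <- set_param(start, "c", value = 6.89)
    for (nm in c("occ_P", "occ_O1", "occ_O2", "occ_O3"))
      start <- set_param(start, nm, value = 0.93)
    start <- refine_only(start, c("a", "c", "occ_P", "occ_O1", "occ_O2",
                                  "occ_O3", "t"))
    res <- refine(obs, start, model, maxiter = 40)
    v <- param_values(res$params)
    err_a <- c(err_a, abs(v[["a"]] - a_true))
    err_c <- c(err_c, abs(v[["c"]] - c_true))
    err_occ <- c(err_occ, abs(v[["occ_P"]] - occ_true))
    err_t <- c(err_t, abs(v[["t"]] - t_true))
  }
  expect_lt(median(err_a), 0.002)
  expect_lt(median(err_c), 0.002)
  expect_lt(median(err_occ), 0.02)
  expect_lt(median(err_t), 3)
})
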