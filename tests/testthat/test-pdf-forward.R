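test_that("effective temperature factor hits its endpoints and is monotone", {
  a <- adp_model(0.4, 1.5, 4)
  expect_equal(beq_effective(0, a), 0.4)
  expect_equal(beq_effective(8, a), 1.5)
  expect_equal(beq_effective(100, a), 1.5)
  r <- seq(0, 10, by = 0.01)
  expect_true(all(diff(beq_effective(r, a)) >= 0))
  expect_error(adp_model(0.4, 1.5, -1), "radius")
  expect_error(adp_model(0.8, 0.4, 4), "beqhi")
})

test_that("the interpolation weight equals the Monte-Carlo sphere-overlap fraction", {
  R <- 4
  a <- adp_model(0.4, 1.5, R)
  for (d in c(1.0, 3.0, 6.0)) {
    mc <- mc_sphere_overlap(d, R, n = 1e6, seed = 11)
    weight <- (a$beqhi - beq_effective(d, a)) / (a$beqhi - a$beqlo)
    expect_lt(abs(weight - mc$estimate), 3 * mc$se + 1e-12)
  }
})

test_that("nanosheet envelope has the slab-autocorrelation form", {
  expect_equal(nanosheet_envelope(0, 30), 1)
  r <- seq(0, 120, by = 0.5)
  env <- nanosheet_envelope(r, 30)
  expect_true(all(env >= 0 & env <= 1))
  expect_true(all(diff(env) <= 0))
  # scale invariance in r/t
  expect_equal(nanosheet_envelope(2 * r, 60), env, tolerance = 1e-12)
  # Monte-Carlo slab autocorrelation
  for (rr in c(5, 20, 45, 80)) {
    mc <- mc_slab_autocorrelation(rr, 30, n = 1e6, seed = 13)
    expect_lt(abs(nanosheet_envelope(rr, 30) - mc$estimate), 3 * mc$se + 1e-12)
  }
  expect_error(nanosheet_envelope(1, -2), "thickness")
})

test_that("a single isolated pair gives the closed-form Gaussian peak", {
  d <- 2.0
  st <- toy_pair_structure(d = d, a = 25, b1 = 0.8, b2 = 1.2,
                           occ1 = 0.9, occ2 = 0.7)
  r <- seq(1, 3.5, by = 0.01)
  g <- calc_gr(st, pdf_grid(r), env = shape_envelope("none"))
  sig <- sqrt((0.8 + 1.2) / (8 * pi^2))
  w1 <- 0.9 * 20; w2 <- 0.7 * 8       # occ * Z for Ca and O
  n_eff <- 0.9 + 0.7
  zbar <- (w1 + w2) / n_eff
  rho0 <- n_eff / 25^3
  expected <- 2 * w1 * w2 * dnorm(r, d, sig) / (n_eff * zbar^2) / r -
    4 * pi * r * rho0
  expect_equal(g$g, expected, tolerance = 1e-8)
})

test_that("calc_gr equals the brute-force supercell double loop", {
  r <- seq(1, 15, by = 0.05)
  st <- toy_mixed_structure()
  # static site ADPs
  expect_lt(max(abs(oracle_calc_gr(st, r) -
                    calc_gr(st, pdf_grid(r), env = shape_envelope("none"))$g)),
            1e-8)
  # r-dependent ADPs, nanosheet envelope, damping and scale
  adp <- list(Ca = adp_model(0.4, 1.2, 3), P = adp_model(0.3, 0.8, 3),
              O = adp_model(0.5, 1.5, 3))
  go <- oracle_calc_gr(st, r, adp = adp, qdamp = 0.04, scale = 2.5,
                       envelope = function(rr) nanosheet_envelope(rr, 25))
  gc <- calc_gr(st, pdf_grid(r), adp = adp,
                env = shape_envelope("nanosheet", 25, 0.04), scale = 2.5)
  expect_lt(max(abs(go - gc$g)), 1e-8)
  # two-site periodic cell as a second case
  st2 <- toy_pair_structure(d = 1.8, a = 6, b1 = 0.6, b2 = 1.0, occ2 = 0.8)
  expect_lt(max(abs(oracle_calc_gr(st2, r) -
                    calc_gr(st2, pdf_grid(r), env = shape_envelope("none"))$g)),
            1e-8)
})

test_that("silicon's first PDF peak sits at the tetrahedral bond distance", {
  a <- 5.4312
  g <- calc_gr(silicon_structure(a), pdf_grid_range(1.5, 3, 0.002),
               adp = list(Si = adp_model(0.3, 0.6, 4)),
               env = shape_envelope("none", qdamp = 0.03))
  rpk <- g$r[which.max(g$g)]
  # the 1/r weighting of G(r) pulls the apparent maximum a few grid steps
  # below the true pair distance
  expect_equal(rpk, a * sqrt(3) / 4, tolerance = 5e-3)
})

test_that("G(r) is linear in scale and oscillates about zero for a bulk crystal", {
  st <- toy_mixed_structure()
  grid <- pdf_grid_range(1, 40, 0.05)
  g1 <- calc_gr(st, grid, env = shape_envelope("none"), scale = 1)
  g2 <- calc_gr(st, grid, env = shape_envelope("none"), scale = 2)
  expect_equal(g2$g, 2 * g1$g, tolerance = 1e-12)
  # bulk: no envelope, qdamp 0; running mean decays towards zero
  expect_lt(abs(mean(g1$g[g1$r > 20])), 0.05 * max(abs(g1$g)))
})

test_that("occupancy scaling: pair sum scales quadratically, density linearly", {
  st <- toy_mixed_structure()
  grid <- pdf_grid(seq(1, 12, 0.05))
  full <- pair_sum_components(st, grid)
  st2 <- st
  st2$sites$occ <- st$sites$occ / 2
  half <- pair_sum_components(st2, grid)
  expect_equal(half$pair_sum, full$pair_sum / 4, tolerance = 1e-10)
  expect_equal(half$rho0, full$rho0 / 2, tolerance = 1e-12)
  expect_equal(half$n_eff, full$n_eff / 2, tolerance = 1e-12)
  expect_equal(half$zbar, full$zbar, tolerance = 1e-12)
})

test_that("constant ADP model reproduces the uncorrelated-ADP curve", {
  st <- toy_mixed_structure()
  grid <- pdf_grid(seq(1, 12, 0.05))
  # set all species to the same constant B as the sites carry
  stB <- st
  stB$sites$b <- 0.9
  adp <- list(Ca = adp_model(0.9, 0.9, 5), P = adp_model(0.9, 0.9, 5),
              O = adp_model(0.9, 0.9, 5))
  g_adp <- calc_gr(stB, grid, adp = adp, env = shape_envelope("none"))
  g_static <- calc_gr(stB, grid, adp = NULL, env = shape_envelope("none"))
  expect_equal(g_adp$g, g_static$g, tolerance = 1e-12)
})

test_that("grid and structure validation errors are explicit", {
  st <- toy_mixed_structure()
  expect_error(pdf_grid(c(1, 1, 2)), "strictly increasing")
  empty <- st; empty$sites <- st$sites[0, ]
  expect_error(calc_gr(empty, pdf_grid(seq(1, 5, 0.1))), "empty structure")
})
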