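test_that("expansion emits the 42-site ordered cell with published multiplicities", {
  st <- hydroxyapatite_structure()
  expect_equal(nrow(st$sites), 42)
  tab <- table(st$sites$site)
  expect_equal(as.integer(tab[c("Ca1", "Ca2", "P", "O1", "O2", "O3", "OH")]),
               c(4, 6, 6, 6, 6, 12, 2))
  # all coordinates reduced
  expect_true(all(st$sites[, c("x", "y", "z")] >= 0 &
                  st$sites[, c("x", "y", "z")] < 1))
})

test_that("wyckoff multiplicities survive arbitrary asymmetric parameters", {
  st <- expand_p1(hexagonal_cell(9.40, 6.90),
                  asym_coordinates(0.41, 0.33, 0.02, 0.27, 0.98, 0.15),
                  rigid_body_spec(1.5, 1.55, 1.48, 107, 113, 125, 233),
                  zrot = 77, occ = occupancy_set(0.9, 0.8, 0.85, 0.95, 1, 1, 0.7),
                  adps = 0.8)
  expect_equal(nrow(st$sites), 42)
  expect_equal(as.integer(table(st$sites$site)[c("Ca1", "Ca2", "P", "O1", "O2", "O3", "OH")]),
               c(4, 6, 6, 6, 6, 12, 2))
})

test_that("z rotation is 360-periodic", {
  s0 <- expand_p1(hexagonal_cell(9.42, 6.89), zrot = 0)
  s360 <- expand_p1(hexagonal_cell(9.42, 6.89), zrot = 360)
  expect_equal(s0$sites[, c("x", "y", "z")], s360$sites[, c("x", "y", "z")],
               tolerance = 1e-12)
})

test_that("the cell is closed under the 6_3 screw generator as a permutation", {
  st <- expand_p1(hexagonal_cell(9.43, 6.89),
                  asym_coordinates(0.39, 0.37, 0.004, 0.25, 0.99, 0.19),
                  rigid_body_spec(1.52, 1.54, 1.50, 110, 109, 118, 244),
                  zrot = 140)
  pos <- as.matrix(st$sites[, c("x", "y", "z")])
  # apply (x, y, z) -> (-x, -y, z + 1/2) to every site
  moved <- cbind(-pos[, 1], -pos[, 2], pos[, 3] + 0.5)
  moved <- moved - floor(moved)
  for (i in seq_len(nrow(moved))) {
    d <- sweep(pos, 2, moved[i, ])
    d <- d - round(d)
    j <- which(rowSums(abs(d)) < 1e-10)
    expect_length(j, 1)
    expect_equal(st$sites$site[j], st$sites$site[i])
  }
})

test_that("the ordered hydroxyl column has no mirror-ambiguous short contact", {
  st <- hydroxyapatite_structure()
  oh <- st$sites[st$sites$site == "OH", ]
  expect_equal(nrow(oh), 2)
  d <- pbc_distance(st$cell, as.numeric(oh[1, c("x", "y", "z")]),
                    as.numeric(oh[2, c("x", "y", "z")]))
  expect_gt(d, 2)
})

test_that("rigid-body geometry survives the P1 expansion on every body", {
  spec <- rigid_body_spec(1.49, 1.56, 1.53, 108, 112, 117, 238)
  st <- expand_p1(hexagonal_cell(9.42, 6.89), asym_coordinates(), spec,
                  zrot = 120)
  for (k in 1:6) {
    labs <- paste0(c("P_", "O1_", "O2_", "O3a_", "O3b_"), k)
    idx <- match(labs, st$sites$label)
    fr <- as.matrix(st$sites[idx, c("x", "y", "z")])
    fr <- sweep(fr, 2, fr[1, ])
    fr <- fr - round(fr)
    xyz <- frac_to_cart(st$cell, sweep(fr, 2, as.matrix(st$sites[idx[1], c("x", "y", "z")]), "+"))
    rownames(xyz) <- c("P", "O1", "O2", "O3a", "O3b")
    m <- measure_rigid_body(xyz)
    expect_equal(unclass(m), unclass(spec), tolerance = 1e-9)
  }
})

test_that("overlapping sites trigger a warning but not an error", {
  # an OH_z of 0.25 puts the channel oxygen onto the mirror plane shared by
  # no other site, so no warning; a contrived Ca2 on top of P does warn
  expect_warning(
    expand_p1(hexagonal_cell(9.42, 6.89),
              asym_coordinates(Ca2_x = 0.3987, Ca2_y = 0.3685)),
    "closer than 0.1")
})

test_that("silicon standard is the 8-atom diamond cell", {
  si <- silicon_structure()
  expect_equal(nrow(si$sites), 8)
  # nearest neighbour at a*sqrt(3)/4
  d <- pbc_distance(si$cell, as.numeric(si$sites[1, c("x", "y", "z")]),
                    as.numeric(si$sites[5, c("x", "y", "z")]))
  expect_equal(d, 5.4312 * sqrt(3) / 4, tolerance = 1e-10)
})

test_that("structures round-trip through CIF", {
  st <- hydroxyapatite_structure(occ = occupancy_set(occ_P = 0.87, occ_OH = 0.62))
  path <- withr::local_tempfile(fileext = ".cif")
  write_cif(st, path)
  back <- read_cif(path)
  expect_equal(back$cell$a, st$cell$a, tolerance = 1e-6)
  expect_equal(back$cell$gamma, 120)
  expect_equal(nrow(back$sites), 42)
  expect_equal(back$sites$x, st$sites$x, tolerance = 1e-6)
  expect_equal(back$sites$occ, st$sites$occ, tolerance = 1e-5)
  expect_equal(back$sites$species, st$sites$species)
})
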