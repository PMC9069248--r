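# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: plain-R vector geometry, explicit
# supercell tiling with full (untruncated) Gaussians, and Monte-Carlo
# geometry estimates.

# --- independent vector geometry -------------------------------------------

oracle_distance <- function(u, v) sqrt(sum((u - v)^2))

oracle_angle <- function(u, p, v) {
  a <- u - p; b <- v - p
  acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
}

# torsion of `atom` about the p -> axis direction measured from the
# half-plane of `ref`, via explicit projection onto an orthonormal frame
oracle_torsion <- function(atom, p, axis, ref) {
  x <- (axis - p) / sqrt(sum((axis - p)^2))
  wr <- (ref - p) - sum((ref - p) * x) * x
  u <- wr / sqrt(sum(wr^2))
  v <- c(x[2] * u[3] - x[3] * u[2],
         x[3] * u[1] - x[1] * u[3],
         x[1] * u[2] - x[2] * u[1])
  w <- (atom - p) - sum((atom - p) * x) * x
  (atan2(sum(w * v), sum(w * u)) * 180 / pi) %% 360
}

# --- brute-force PDF pair sum ----------------------------------------------

# G(r) by a literal double loop over an explicitly tiled supercell with
# full Gaussians (no truncation).  Matches the conventions documented for
# calc_gr: w_i = occ_i * Z_i, normalisation N <Z>^2, rho0 = sum(occ)/V.
oracle_calc_gr <- function(structure, r, adp = NULL, qdamp = 0, scale = 1,
                           envelope = NULL) {
  s <- structure$sites
  L <- apatitepdf::lattice_matrix(structure$cell)
  cart <- t(L %*% t(as.matrix(s[, c("x", "y", "z")])))
  z <- apatitepdf:::species_z(s$species)
  w <- s$occ * z

  beff <- function(d, sp, i) {
    if (is.null(adp)) return(s$b[i])
    m <- adp[[sp]]
    if (d >= 2 * m$radius) return(m$beqhi)
    frac <- 1 - 3 * d / (4 * m$radius) + d^3 / (16 * m$radius^3)
    m$beqhi - (m$beqhi - m$beqlo) * frac
  }

  rmax <- max(r)
  # generous tiling: enough whole cells to cover rmax in every direction
  ncell <- ceiling(rmax / min(sqrt(colSums(L^2)))) + 2
  shifts <- as.matrix(expand.grid(-ncell:ncell, -ncell:ncell, -ncell:ncell))
  gsum <- numeric(length(r))
  n <- nrow(s)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(nrow(shifts))) {
        tvec <- L %*% shifts[k, ]
        d <- sqrt(sum((cart[j, ] + tvec - cart[i, ])^2))
        if (d < 1e-8 || d > rmax + 5) next
        s2 <- (beff(d, s$species[i], i) + beff(d, s$species[j], j)) / (8 * pi^2)
        gsum <- gsum + w[i] * w[j] * dnorm(r, mean = d, sd = sqrt(s2))
      }
    }
  }
  n_eff <- sum(s$occ)
  zbar <- sum(w) / n_eff
  rho0 <- n_eff / apatitepdf::cell_volume(structure$cell)
  g0 <- gsum / (n_eff * zbar^2) / r - 4 * pi * r * rho0
  env <- if (is.null(envelope)) 1 else envelope(r)
  scale * env * exp(-(qdamp * r)^2 / 2) * g0
}

# --- Monte-Carlo geometry oracles ------------------------------------------

# overlap volume fraction of two spheres of radius R at separation d,
# estimated by sampling points uniformly in one sphere
mc_sphere_overlap <- function(d, R, n = 1e6, seed = 1) {
  set.seed(seed)
  # uniform in sphere via rejection-free radius sampling
  u <- runif(n)
  rad <- R * u^(1 / 3)
  costh <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  sinth <- sqrt(1 - costh^2)
  x <- rad * sinth * cos(phi); y <- rad * sinth * sin(phi); z <- rad * costh
  inside <- (x - d)^2 + y^2 + z^2 <= R^2
  p <- mean(inside)
  list(estimate = p, se = sqrt(p * (1 - p) / n))
}

# orientation-averaged probability that a displacement of length r from a
# uniform point in an infinite slab of thickness t stays inside the slab
mc_slab_autocorrelation <- function(r, t, n = 1e6, seed = 1) {
  set.seed(seed)
  z0 <- runif(n, 0, t)
  costh <- runif(n, -1, 1)
  z1 <- z0 + r * costh
  p <- mean(z1 >= 0 & z1 <= t)
  list(estimate = p, se = sqrt(p * (1 - p) / n))
}

# --- closed-form OLS --------------------------------------------------------

oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  tstat <- slope / se_slope
  p <- 2 * pt(-abs(tstat), df = n - 2)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, p = p,
       r2 = r2, r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
       corr = sign(slope) * sqrt(r2))
}

# --- shared toy structures --------------------------------------------------

# minimal two-site structure in a roomy cell (isolated pair for closed-form
# checks); b values positive so the Gaussian widths are defined
toy_pair_structure <- function(d = 2.0, a = 20, b1 = 0.8, b2 = 1.2,
                               occ1 = 1, occ2 = 1) {
  sites <- data.frame(label = c("A_1", "B_1"), species = c("Ca", "O"),
                      site = c("A", "B"),
                      x = c(0.1, 0.1 + d / a), y = c(0.1, 0.1), z = c(0.1, 0.1),
                      occ = c(occ1, occ2), b = c(b1, b2),
                      stringsAsFactors = FALSE)
  structure(list(cell = apatitepdf::cubic_cell(a), sites = sites,
                 provenance = list(kind = "toy")),
            class = "p1_structure")
}

# small low-symmetry 4-site cell exercising species, occupancy and ADP
# diversity in the oracle comparison
toy_mixed_structure <- function() {
  sites <- data.frame(
    label = c("Ca_1", "P_1", "O_1", "O_2"),
    species = c("Ca", "P", "O", "O"),
    site = c("Ca", "P", "O", "O"),
    x = c(0.05, 0.40, 0.75, 0.20),
    y = c(0.10, 0.55, 0.30, 0.80),
    z = c(0.15, 0.25, 0.60, 0.45),
    occ = c(1.0, 0.8, 0.9, 0.5),
    b = c(0.7, 0.5, 1.1, 0.9),
    stringsAsFactors = FALSE)
  structure(list(cell = apatitepdf::unit_cell(6.1, 6.1, 4.7, 90, 90, 120),
                 sites = sites, provenance = list(kind = "toy")),
            class = "p1_structure")
}
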