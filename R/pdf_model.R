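#' r-dependent correlated-motion temperature factor
#'
#' Correlated motion of near neighbours sharpens short-r PDF peaks.  The
#' effective isotropic temperature factor B(r) equals `beqlo` at r = 0 and
#' `beqhi` for r >= 2*radius, interpolating in between with the overlap
#' volume fraction of two spheres of radius `radius` whose centres are r
#' apart: B(r) = beqhi - (beqhi - beqlo) * (1 - 3r/(4R) + r^3/(16R^3)).
#'
#' @param beqlo B at zero separation, angstrom^2 (> 0)
#' @param beqhi B at and beyond twice the correlation radius, angstrom^2
#'   (>= beqlo)
#' @param radius correlation radius R, angstrom (> 0)
#' @return object of class `adp_model`
#' @export
adp_model <- function(beqlo, beqhi, radius) {
  if (radius <= 0) stop("correlation radius must be positive")
  if (beqlo <= 0) stop("beqlo must be positive")
  if (beqhi < beqlo) stop("beqhi must be >= beqlo (correlated motion sharpens short-r peaks)")
  structure(list(beqlo = beqlo, beqhi = beqhi, radius = radius), class = "adp_model")
}

#' @rdname adp_model
#' @param r pair distance(s), angstrom (>= 0)
#' @param adp an [adp_model()]
#' @return effective B value(s), angstrom^2
#' @export
#' @examples
#' a <- adp_model(0.4, 1.5, 4)
#' beq_effective(0, a)             # 0.4
#' beq_effective(8, a)             # 1.5
beq_effective <- function(r, adp) {
  stopifnot(inherits(adp, "adp_model"), all(r >= 0))
  R <- adp$radius
  w <- ifelse(r >= 2 * R, 0, 1 - 3 * r / (4 * R) + r^3 / (16 * R^3))
  adp$beqhi - (adp$beqhi - adp$beqlo) * w
}

#' Nanosheet shape damping envelope
#'
#' Orientation-averaged autocorrelation of an infinite slab of thickness
#' `t`: the fraction of pair vectors of length r whose both ends fall
#' inside the sheet,
#' `1 - r/(2t)` for `r <= t` and `t/(2r)` beyond.  Multiplies the model
#' G(r) of platy nanocrystals; equals 1 at r = 0 and decays monotonically.
#'
#' @param r distance(s), angstrom (>= 0)
#' @param t sheet thickness, angstrom (> 0)
#' @return attenuation factor in `[0, 1]`
#' @export
#' @examples
#' nanosheet_envelope(0, 30)    # 1
#' nanosheet_envelope(60, 30)   # 0.25
nanosheet_envelope <- function(r, t) {
  if (t <= 0) stop("sheet thickness must be positive")
  stopifnot(all(r >= 0))
  ifelse(r <= t, 1 - r / (2 * t), t / (2 * r))
}

#' Shape envelope specification
#'
#' @param kind `"none"` (bulk crystal) or `"nanosheet"`
#' @param t sheet thickness, angstrom (required for `"nanosheet"`)
#' @param qdamp instrumental damping coefficient, 1/angstrom; applied as
#'   the Gaussian envelope exp(-(qdamp*r)^2/2)
#' @export
shape_envelope <- function(kind = c("none", "nanosheet"), t = NA_real_, qdamp = 0) {
  kind <- match.arg(kind)
  if (kind == "nanosheet" && (!is.finite(t) || t <= 0))
    stop("nanosheet envelope requires a positive thickness t")
  if (qdamp < 0) stop("qdamp must be >= 0")
  structure(list(kind = kind, t = t, qdamp = qdamp), class = "shape_envelope")
}

envelope_values <- function(env, r) {
  sh <- if (env$kind == "nanosheet") nanosheet_envelope(r, env$t) else rep(1, length(r))
  sh * exp(-(env$qdamp * r)^2 / 2)
}

#' PDF grid container
#'
#' A pair distribution function sampled on a strictly increasing r grid,
#' with the Q-range metadata of the reduction carried along.
#'
#' @param r distances, angstrom, strictly increasing, `r >= 0`
#' @param g G(r) values (1/angstrom^2); defaults to zeros for a grid
#'   awaiting calculation
#' @param qmin,qmax momentum-transfer range of the underlying reduction,
#'   1/angstrom (metadata)
#' @return object of class `pdf_grid` with fields `r`, `g`, `qmin`, `qmax`
#' @export
pdf_grid <- function(r, g = numeric(length(r)), qmin = 0.5, qmax = 25.6) {
  stopifnot(is.numeric(r), length(r) >= 2, all(is.finite(r)))
  if (any(diff(r) <= 0)) stop("r grid must be strictly increasing")
  if (r[1] < 0) stop("r must be non-negative")
  if (length(g) != length(r)) stop("g must match r in length")
  structure(list(r = r, g = g, qmin = qmin, qmax = qmax), class = "pdf_grid")
}

#' @rdname pdf_grid
#' @param rmin,rmax,step fit-range construction helper, angstrom
#' @export
pdf_grid_range <- function(rmin = 1, rmax = 50, step = 0.05, qmin = 0.5, qmax = 25.6) {
  pdf_grid(seq(rmin, rmax, by = step), qmin = qmin, qmax = qmax)
}

#' @export
print.pdf_grid <- function(x, ...) {
  cat(sprintf("PDF grid: %d points, r = %.2f..%.2f A (step %.4g), Q = %.2f..%.2f 1/A\n",
              length(x$r), min(x$r), max(x$r), x$r[2] - x$r[1], x$qmin, x$qmax))
  invisible(x)
}

#' Calculate the model pair distribution function
#'
#' Computes G(r) for a structure on the grid:
#' `G(r) = scale * envelope(r) * exp(-(qdamp r)^2 / 2) * (R(r)/r - 4 pi r rho0)`
#' where `R(r)` is the weighted radial pair sum over all periodic pairs,
#' each pair broadened by a Gaussian of variance `(B_i(d) + B_j(d)) /
#' (8 pi^2)` with the r-dependent effective B evaluated at the pair
#' distance, and `rho0` is the occupancy-weighted number density.  Weights
#' are the X-ray atomic-number approximation: `w_i = occ_i Z_i`, the pair
#' sum is normalised by `N <Z>^2` with `N = sum(occ)` and
#' `<Z> = sum(occ Z)/N`.  Hydrogen never enters (the model carries no H
#' sites).
#'
#' @param structure a `p1_structure`
#' @param grid a [pdf_grid()] (its `g` is ignored); must be uniform
#' @param adp either a single [adp_model()] shared by all species, or a
#'   named list of `adp_model`s keyed by species (`Ca`, `P`, `O`, `Si`,
#'   ...).  When `NULL`, each site's static `b` column is used at all r
#'   (uncorrelated ADPs).
#' @param env a [shape_envelope()]
#' @param scale overall scale factor
#' @return a [pdf_grid()] carrying the calculated G(r)
#' @export
#' @examples
#' g <- calc_gr(silicon_structure(), pdf_grid_range(1, 10, 0.05),
#'              env = shape_envelope("none", qdamp = 0.03))
calc_gr <- function(structure, grid, adp = NULL,
                    env = shape_envelope("none"), scale = 1) {
  stopifnot(inherits(structure, "p1_structure"), inherits(grid, "pdf_grid"),
            inherits(env, "shape_envelope"))
  s <- structure$sites
  if (nrow(s) == 0) stop("empty structure")
  comp <- pair_sum_components(structure, grid, adp)
  g0 <- comp$pair_sum / (comp$n_eff * comp$zbar^2) / grid$r -
    4 * pi * grid$r * comp$rho0
  pdf_grid(grid$r, scale * envelope_values(env, grid$r) * g0,
           qmin = grid$qmin, qmax = grid$qmax)
}

#' Raw components of the PDF pair sum
#'
#' Exposes the unnormalised weighted pair density `pair_sum(r)` (sum over
#' ordered periodic pairs of `occ_i Z_i occ_j Z_j` Gaussians), the
#' effective atom count `n_eff = sum(occ)`, the weighted mean atomic
#' number `zbar` and the number density `rho0 = n_eff / V`.  Useful for
#' testing the occupancy scaling of the components separately.
#'
#' @inheritParams calc_gr
#' @export
pair_sum_components <- function(structure, grid, adp = NULL) {
  s <- structure$sites
  cart <- frac_to_cart(structure$cell, as.matrix(s[, c("x", "y", "z")]))
  w <- s$occ * species_z(s$species)

  if (is.null(adp)) {
    # static per-site B: constant in r (beqlo = beqhi), tiny radius
    blo <- s$b; bhi <- s$b; rad <- rep(1, nrow(s))
    if (any(s$b <= 0)) stop("all site B values must be positive")
    bmax <- max(s$b)
  } else {
    if (inherits(adp, "adp_model")) {
      adp <- setNames(rep(list(adp), length(unique(s$species))), unique(s$species))
    }
    if (!all(s$species %in% names(adp)))
      stop("adp list must cover species: ", paste(unique(s$species), collapse = ", "))
    blo <- vapply(s$species, function(sp) adp[[sp]]$beqlo, numeric(1))
    bhi <- vapply(s$species, function(sp) adp[[sp]]$beqhi, numeric(1))
    rad <- vapply(s$species, function(sp) adp[[sp]]$radius, numeric(1))
    bmax <- max(bhi)
  }

  sig_max <- sqrt(2 * bmax / (8 * pi^2))
  cutoff <- max(grid$r) + 8 * sig_max + 0.1
  L <- lattice_matrix(structure$cell)
  # image counts per axis from the interplanar spacings of the lattice
  Linv <- solve(L)
  d_spacing <- 1 / sqrt(rowSums(Linv^2))
  nmax <- as.integer(ceiling(cutoff / d_spacing) + 1)

  ps <- pair_density_cpp(cart, w, blo, bhi, rad, L, nmax, grid$r, cutoff)
  n_eff <- sum(s$occ)
  zbar <- sum(w) / n_eff
  list(pair_sum = ps, n_eff = n_eff, zbar = zbar,
       rho0 = n_eff / cell_volume(structure$cell))
}
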