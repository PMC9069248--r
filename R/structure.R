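#' Asymmetric-unit coordinates of the apatite model
#'
#' The six refinable fractional coordinates of the ordered P1 apatite cell:
#' phosphorus x/y (z fixed on the mirror plane), Ca1 z, Ca2 x/y (z on the
#' mirror plane) and the hydroxyl oxygen z in the c-axis channel.  Defaults
#' are literature single-crystal hydroxyapatite values.
#'
#' @param P_x,P_y fractional coordinates of phosphorus
#' @param Ca1_z fractional z of the columnar calcium
#' @param Ca2_x,Ca2_y fractional coordinates of the triangular calcium
#' @param OH_z fractional z of the channel hydroxyl oxygen
#' @return object of class `asym_coordinates`
#' @export
asym_coordinates <- function(P_x = 0.3987, P_y = 0.3685, Ca1_z = 0.0010,
                             Ca2_x = 0.2466, Ca2_y = 0.9931, OH_z = 0.1930) {
  v <- c(P_x = P_x, P_y = P_y, Ca1_z = Ca1_z, Ca2_x = Ca2_x,
         Ca2_y = Ca2_y, OH_z = OH_z)
  v <- wrap_frac(v)
  structure(as.list(v), class = "asym_coordinates")
}

#' Per-species site occupancies
#'
#' Fractional occupancies of the seven independent sites.  The three O
#' sites of the phosphate rigid body carry their own occupancies (they may
#' be linked to `occ_P` during refinement but are reported separately).
#'
#' @param occ_P,occ_O1,occ_O2,occ_O3,occ_Ca1,occ_Ca2,occ_OH fractions in
#'   `[0, 1]`
#' @return object of class `occupancy_set`
#' @export
occupancy_set <- function(occ_P = 1, occ_O1 = 1, occ_O2 = 1, occ_O3 = 1,
                          occ_Ca1 = 1, occ_Ca2 = 1, occ_OH = 1) {
  v <- c(occ_P = occ_P, occ_O1 = occ_O1, occ_O2 = occ_O2, occ_O3 = occ_O3,
         occ_Ca1 = occ_Ca1, occ_Ca2 = occ_Ca2, occ_OH = occ_OH)
  if (any(v < 0) || any(v > 1)) stop("occupancies must lie in [0, 1]")
  structure(as.list(v), class = "occupancy_set")
}

# proper symmetry operators of the P6_3 subgroup, acting on fractional
# coordinates; these generate the six phosphate bodies without reflecting
# them (the out-of-plane O3 atoms are explicit, so mirror images must not
# be re-generated)
.p63_ops <- function() {
  rot <- list(diag(3),
              matrix(c(0, 1, 0, -1, -1, 0, 0, 0, 1), 3, byrow = FALSE),
              matrix(c(-1, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = FALSE))
  ops <- list()
  for (R in rot) {
    ops[[length(ops) + 1]] <- list(R = R, t = c(0, 0, 0))
    ops[[length(ops) + 1]] <- list(R = -R * c(1, 1, -1), t = c(0, 0, 0.5))
  }
  ops
}

# full P6_3/m operator set: the proper six plus each composed with the
# mirror z -> 1/2 - z (plane at z = 1/4)
.p63m_ops <- function() {
  ops <- .p63_ops()
  mirror <- function(op) {
    # m: (x, y, z) -> (x, y, 1/2 - z) composed after op
    R <- op$R; t <- op$t
    Rm <- R; Rm[3, ] <- -R[3, ]
    tm <- t; tm[3] <- 0.5 - t[3]
    list(R = Rm, t = tm)
  }
  c(ops, lapply(ops, mirror))
}

.apply_op <- function(op, frac) wrap_frac(as.numeric(op$R %*% frac + op$t))

# orbit of a fractional position under an operator list, deduplicated
.orbit <- function(frac, ops, tol = 1e-6) {
  pos <- t(vapply(ops, .apply_op, numeric(3), frac = frac))
  keep <- rep(TRUE, nrow(pos))
  for (i in seq_len(nrow(pos))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      d <- pos[i, ] - pos[j, ]
      d <- d - round(d)
      if (all(abs(d) < tol)) { keep[i] <- FALSE; break }
    }
  }
  pos[keep, , drop = FALSE]
}

#' Expand the ordered P1 apatite cell
#'
#' Applies the hexagonal-apatite generators to the asymmetric parameters
#' and returns an explicit P1 cell of 42 non-hydrogen sites: 4 Ca1, 6 Ca2
#' and six phosphate rigid bodies (6 P, 6 O1, 6 O2, 12 O3) plus an ordered
#' two-site hydroxyl column.  The calcium orbits use the full P6_3/m
#' operator set; the phosphate bodies and the hydroxyl column use only the
#' proper P6_3 operators, so each of the six bodies is a congruent copy
#' (no mirror images) and the channel holds exactly one oxygen per z = 1/4
#' and z = 3/4 position.  This single-orientation ordered choice removes
#' the spurious short O(H)...O(H) vectors that a half-occupied mirror pair
#' would imprint on the calculated G(r).
#'
#' @param cell a [hexagonal_cell()]
#' @param coords an [asym_coordinates()]
#' @param spec a [rigid_body_spec()]
#' @param zrot rotation of the phosphate body about the crystallographic z
#'   axis, degrees
#' @param occ an [occupancy_set()]
#' @param adps named per-species isotropic B values (angstrom^2) with names
#'   among Ca1, Ca2, P, O1, O2, O3, OH; a single unnamed number is recycled
#' @param check_overlap warn when two emitted sites come closer than 0.1
#'   angstrom; disable inside refinement loops where the geometry has
#'   already been validated
#' @return object of class `p1_structure`: list with `cell` and `sites`
#'   (data.frame: label, species, site, x, y, z fractional, occ, b)
#' @export
#' @examples
#' st <- expand_p1(hexagonal_cell(9.4227, 6.8886), asym_coordinates(),
#'                 ha_rigid_body_spec(), zrot = 141.95)
#' nrow(st$sites)  # 42
expand_p1 <- function(cell, coords = asym_coordinates(),
                      spec = ha_rigid_body_spec(), zrot = 141.95,
                      occ = occupancy_set(), adps = 1.0, check_overlap = TRUE) {
  stopifnot(inherits(cell, "unit_cell"), inherits(coords, "asym_coordinates"),
            inherits(spec, "rigid_body_spec"), inherits(occ, "occupancy_set"))
  site_names <- c("Ca1", "Ca2", "P", "O1", "O2", "O3", "OH")
  if (length(adps) == 1 && is.null(names(adps)))
    adps <- setNames(rep(adps, 7), site_names)
  if (!all(site_names %in% names(adps)))
    stop("adps must name all of: ", paste(site_names, collapse = ", "))

  zr <- (zrot %% 360) * pi / 180
  Rz <- matrix(c(cos(zr), sin(zr), 0, -sin(zr), cos(zr), 0, 0, 0, 1), 3)
  body <- build_rigid_body(spec) %*% t(Rz)
  p_frac <- c(coords$P_x, coords$P_y, 0.25)
  body_frac <- sweep(cart_to_frac(cell, body), 2, p_frac, "+")
  rownames(body_frac) <- rownames(build_rigid_body(spec))

  ops6 <- .p63_ops()
  ops12 <- .p63m_ops()

  rows <- list()
  add <- function(label, species, site, pos, occv, b) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = label, species = species, site = site,
      x = pos[, 1], y = pos[, 2], z = pos[, 3], occ = occv, b = b,
      stringsAsFactors = FALSE)
  }

  ca1 <- .orbit(c(1 / 3, 2 / 3, coords$Ca1_z), ops12)
  add(paste0("Ca1_", seq_len(nrow(ca1))), "Ca", "Ca1", ca1, occ$occ_Ca1, adps[["Ca1"]])
  ca2 <- .orbit(c(coords$Ca2_x, coords$Ca2_y, 0.25), ops12)
  add(paste0("Ca2_", seq_len(nrow(ca2))), "Ca", "Ca2", ca2, occ$occ_Ca2, adps[["Ca2"]])

  atom_site <- c(P = "P", O1 = "O1", O2 = "O2", O3a = "O3", O3b = "O3")
  atom_occ <- c(P = occ$occ_P, O1 = occ$occ_O1, O2 = occ$occ_O2,
                O3a = occ$occ_O3, O3b = occ$occ_O3)
  for (atom in rownames(body_frac)) {
    pos <- t(vapply(ops6, .apply_op, numeric(3), frac = body_frac[atom, ]))
    site <- atom_site[[atom]]
    species <- if (atom == "P") "P" else "O"
    add(paste0(atom, "_", seq_len(nrow(pos))), species, site, pos,
        atom_occ[[atom]], adps[[site]])
  }

  oh <- .orbit(c(0, 0, coords$OH_z), ops6)
  add(paste0("OH_", seq_len(nrow(oh))), "O", "OH", oh, occ$occ_OH, adps[["OH"]])

  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  st <- structure(list(cell = cell, sites = sites,
                       provenance = list(coords = coords, spec = spec,
                                         zrot = zrot %% 360, occ = occ,
                                         adps = adps)),
                  class = "p1_structure")
  if (!check_overlap) return(st)
  ov <- .overlap_pairs(st)
  if (nrow(ov) > 0)
    warning(sprintf("%d site pair(s) closer than 0.1 A (first: %s-%s at %.3f A)",
                    nrow(ov), ov$a[1], ov$b[1], ov$d[1]))
  st
}

.overlap_pairs <- function(st, tol = 0.1) {
  s <- st$sites
  n <- nrow(s)
  out <- data.frame(a = character(), b = character(), d = numeric())
  fr <- as.matrix(s[, c("x", "y", "z")])
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- pbc_distance(st$cell, fr[i, ], fr[j, ])
      if (d < tol) out <- rbind(out, data.frame(a = s$label[i], b = s$label[j], d = d))
    }
  }
  out
}

#' @export
print.p1_structure <- function(x, ...) {
  cat(sprintf("P1 structure: %d sites in cell a = %.4f, c = %.4f A\n",
              nrow(x$sites), x$cell$a, x$cell$c))
  tab <- table(x$sites$site)
  cat("  sites:", paste(names(tab), tab, sep = " x", collapse = ", "), "\n")
  invisible(x)
}

#' Ordered P1 hydroxyapatite with literature coordinates
#'
#' Convenience constructor: the Kay-type hydroxyapatite cell at chosen (or
#' certified reference) lattice parameters with literature fractional
#' coordinates and rigid-body geometry.
#'
#' @param a,c lattice parameters, angstrom (defaults: certified values of
#'   the NIST SRM 2910b calcium hydroxyapatite reference)
#' @param occ an [occupancy_set()]
#' @param adps per-species B values, see [expand_p1()]
#' @param ... passed on to [expand_p1()]
#' @export
hydroxyapatite_structure <- function(a = 9.4227, c = 6.8886,
                                     occ = occupancy_set(),
                                     adps = ha_default_adps(), ...) {
  expand_p1(hexagonal_cell(a, c), asym_coordinates(), ha_rigid_body_spec(),
            zrot = 141.95, occ = occ, adps = adps, ...)
}

#' Default per-site isotropic B values for hydroxyapatite (angstrom^2)
#' @export
ha_default_adps <- function() {
  c(Ca1 = 0.7, Ca2 = 0.7, P = 0.6, O1 = 1.0, O2 = 1.0, O3 = 1.0, OH = 1.2)
}

#' Diamond-structure silicon
#'
#' Eight-atom conventional cubic cell; default lattice constant is the
#' certified value of the NIST SRM 640c silicon line-position standard.
#' Used to calibrate the instrumental damping coefficient.
#'
#' @param a cubic lattice constant, angstrom
#' @param b_iso isotropic B value, angstrom^2
#' @export
silicon_structure <- function(a = 5.4312, b_iso = 0.5) {
  fcc <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  basis <- rbind(c(0, 0, 0), c(0.25, 0.25, 0.25))
  pos <- do.call(rbind, lapply(seq_len(nrow(basis)), function(i)
    wrap_frac(sweep(fcc, 2, basis[i, ], "+"))))
  sites <- data.frame(label = paste0("Si_", seq_len(nrow(pos))),
                      species = "Si", site = "Si",
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      occ = 1, b = b_iso, stringsAsFactors = FALSE)
  structure(list(cell = cubic_cell(a), sites = sites,
                 provenance = list(kind = "silicon", a = a, b_iso = b_iso)),
            class = "p1_structure")
}

#' Extract one phosphate body's Cartesian coordinates from a structure
#'
#' Returns the first rigid body (labels P_1, O1_1, O2_1, O3a_1, O3b_1) as a
#' 5 x 3 Cartesian matrix suitable for [measure_rigid_body()].
#'
#' @param st a `p1_structure` built by [expand_p1()]
#' @export
first_phosphate_body <- function(st) {
  labs <- c(P = "P_1", O1 = "O1_1", O2 = "O2_1", O3a = "O3a_1", O3b = "O3b_1")
  idx <- match(labs, st$sites$label)
  if (anyNA(idx)) stop("structure does not contain a labelled phosphate body")
  fr <- as.matrix(st$sites[idx, c("x", "y", "z")])
  # unwrap the body around its phosphorus so bonds are not split by the
  # periodic boundary
  pf <- fr[1, ]
  fr <- sweep(fr, 2, pf)
  fr <- fr - round(fr)
  xyz <- frac_to_cart(st$cell, sweep(fr, 2, pf, "+"))
  rownames(xyz) <- names(labs)
  colnames(xyz) <- c("x", "y", "z")
  xyz
}
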