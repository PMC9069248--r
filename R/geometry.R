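#' Vector geometry helpers
#'
#' Interatomic distance, bond angle, and the torsion of an atom about an
#' axis measured from a reference half-plane.  These are the measurement
#' counterparts of the rigid-body constructor and are used to read bond
#' lengths, O--P--O angles and O3 torsions back out of Cartesian or expanded
#' P1 coordinates.
#'
#' @param u,v,p Cartesian positions (numeric length 3)
#' @return distance in angstrom, angle in degrees
#' @name geometry
NULL

#' @rdname geometry
#' @export
bond_length <- function(u, v) sqrt(sum((u - v)^2))

#' @rdname geometry
#' @description `bond_angle(u, p, v)` is the angle u--p--v at vertex `p`.
#' @export
bond_angle <- function(u, p, v) {
  a <- u - p; b <- v - p
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-length bond in angle computation")
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Torsion of an atom about an axis, from a reference half-plane
#'
#' Measures the angle, in `[0, 360)` degrees counter-clockwise about the
#' axis `p -> axis_atom` (right-hand rule), from the half-plane containing
#' `ref_atom` to the half-plane containing `atom`.  With
#' `torsion_about_axis(O3, P, O1, O2)` this is the torsion of O3 about the
#' P--O1 axis measured from the O1--P--O2 plane, i.e. the rigid-body torsion
#' parameter.
#'
#' @param atom atom whose torsion is measured
#' @param p vertex (phosphorus)
#' @param axis_atom atom defining the rotation axis from `p`
#' @param ref_atom atom defining the zero half-plane
#' @return torsion angle, degrees in `[0, 360)`
#' @export
torsion_about_axis <- function(atom, p, axis_atom, ref_atom) {
  x <- axis_atom - p
  nx <- sqrt(sum(x^2))
  if (nx == 0) stop("degenerate axis in torsion computation")
  x <- x / nx
  wr <- (ref_atom - p) - sum((ref_atom - p) * x) * x
  nwr <- sqrt(sum(wr^2))
  if (nwr < 1e-12)
    stop("degenerate geometry: reference atom collinear with the torsion axis")
  u <- wr / nwr
  v <- c(x[2] * u[3] - x[3] * u[2],
         x[3] * u[1] - x[1] * u[3],
         x[1] * u[2] - x[2] * u[1])
  w <- (atom - p) - sum((atom - p) * x) * x
  if (sqrt(sum(w^2)) < 1e-12) return(0)
  (atan2(sum(w * v), sum(w * u)) * 180 / pi) %% 360
}

# trapezoidal integral of y over x
trapz_area <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
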