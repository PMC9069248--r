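#' Rigid-body parameterisation of the phosphate tetrahedron
#'
#' The PO4 anion is modelled as a five-atom rigid body (P, O1, O2, O3a,
#' O3b) described by three bond lengths, the O1--P--O2 and O1--P--O3
#' angles, and the torsions of O3a and O3b about the P--O1 axis measured
#' from the O1--P--O2 plane.  P, O1 and O2 lie in the local xy plane, which
#' coincides with the crystallographic mirror plane once the body is placed
#' in the cell.  An ideal tetrahedron has all bonds 1.52 angstrom, both
#' angles 109.5 degrees and torsions 120/240 degrees.
#'
#' @param d_PO1,d_PO2,d_PO3 P--O bond lengths, angstrom (O3a and O3b share
#'   `d_PO3`)
#' @param ang_O1PO2,ang_O1PO3 O--P--O angles, degrees in (0, 180)
#' @param tors_O3a,tors_O3b torsions of O3a/O3b about the P--O1 axis from
#'   the O2 half-plane, degrees in `[0, 360)`
#' @return object of class `rigid_body_spec`
#' @export
#' @examples
#' rigid_body_spec()                      # ideal tetrahedron
#' build_rigid_body(rigid_body_spec())
rigid_body_spec <- function(d_PO1 = 1.52, d_PO2 = 1.52, d_PO3 = 1.52,
                            ang_O1PO2 = 109.5, ang_O1PO3 = 109.5,
                            tors_O3a = 120, tors_O3b = 240) {
  if (any(c(d_PO1, d_PO2, d_PO3) < 0)) stop("bond lengths must be >= 0")
  if (any(c(ang_O1PO2, ang_O1PO3) <= 0) || any(c(ang_O1PO2, ang_O1PO3) >= 180))
    stop("O-P-O angles must lie in (0, 180) degrees")
  tors_O3a <- tors_O3a %% 360
  tors_O3b <- tors_O3b %% 360
  structure(list(d_PO1 = d_PO1, d_PO2 = d_PO2, d_PO3 = d_PO3,
                 ang_O1PO2 = ang_O1PO2, ang_O1PO3 = ang_O1PO3,
                 tors_O3a = tors_O3a, tors_O3b = tors_O3b),
            class = "rigid_body_spec")
}

#' Rigid-body spec of the literature hydroxyapatite phosphate
#'
#' Bond lengths, angles and torsions measured from the classic single-crystal
#' hydroxyapatite coordinates (Kay-type P6_3/m structure); used as the
#' default starting geometry for refinement and for synthetic truth.
#'
#' @export
ha_rigid_body_spec <- function() {
  rigid_body_spec(d_PO1 = 1.5370, d_PO2 = 1.5416, d_PO3 = 1.5309,
                  ang_O1PO2 = 111.16, ang_O1PO3 = 111.28,
                  tors_O3a = 119.91, tors_O3b = 240.09)
}

#' Build the five-atom phosphate rigid body in its local frame
#'
#' Local frame convention: P at the origin, O1 on the local +x axis, O2 in
#' the local xy plane rotated clockwise (viewed from +z) by `ang_O1PO2`
#' from O1.  O3a/O3b are generated at polar angle `ang_O1PO3` from the
#' P--O1 axis with their torsions measured counter-clockwise about that
#' axis from the O2 half-plane, so that the ideal torsions 120/240 degrees
#' place them symmetrically below/above the plane.  The convention
#' reproduces the handedness of the literature apatite phosphate.
#'
#' @param spec a [rigid_body_spec()]
#' @return 5 x 3 numeric matrix of Cartesian positions (angstrom) with
#'   rownames P, O1, O2, O3a, O3b
#' @export
build_rigid_body <- function(spec) {
  stopifnot(inherits(spec, "rigid_body_spec"))
  d2r <- pi / 180
  a12 <- spec$ang_O1PO2 * d2r
  a13 <- spec$ang_O1PO3 * d2r
  P  <- c(0, 0, 0)
  O1 <- c(spec$d_PO1, 0, 0)
  O2 <- spec$d_PO2 * c(cos(a12), -sin(a12), 0)
  # torsion frame about the P-O1 axis (+x): u points toward the O2
  # half-plane, v = x cross u
  u <- c(0, -1, 0)
  v <- c(0, 0, -1)
  o3 <- function(tors) {
    t <- tors * d2r
    spec$d_PO3 * (cos(a13) * c(1, 0, 0) + sin(a13) * (cos(t) * u + sin(t) * v))
  }
  xyz <- rbind(P = P, O1 = O1, O2 = O2, O3a = o3(spec$tors_O3a), O3b = o3(spec$tors_O3b))
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Measure rigid-body parameters from five Cartesian positions
#'
#' Inverse of [build_rigid_body()]: recomputes the three bond lengths, two
#' angles and two torsions from labelled coordinates.  Also used to read
#' rigid-body geometry out of an expanded P1 structure.
#'
#' @param xyz 5 x 3 matrix with rownames P, O1, O2, O3a, O3b
#' @return a [rigid_body_spec()]
#' @export
measure_rigid_body <- function(xyz) {
  need <- c("P", "O1", "O2", "O3a", "O3b")
  if (!all(need %in% rownames(xyz))) stop("xyz must have rows P, O1, O2, O3a, O3b")
  P <- xyz["P", ]; O1 <- xyz["O1", ]; O2 <- xyz["O2", ]
  O3a <- xyz["O3a", ]; O3b <- xyz["O3b", ]
  rigid_body_spec(
    d_PO1 = bond_length(P, O1),
    d_PO2 = bond_length(P, O2),
    d_PO3 = (bond_length(P, O3a) + bond_length(P, O3b)) / 2,
    ang_O1PO2 = bond_angle(O1, P, O2),
    ang_O1PO3 = (bond_angle(O1, P, O3a) + bond_angle(O1, P, O3b)) / 2,
    tors_O3a = torsion_about_axis(O3a, P, O1, O2),
    tors_O3b = torsion_about_axis(O3b, P, O1, O2)
  )
}
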