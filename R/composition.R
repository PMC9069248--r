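#' Charge-balanced carbonate substitution model
#'
#' B-type carbonate substitution with a phosphorus-site vacancy: one
#' CO3^2- replaces one PO4^3-, and electroneutrality is restored by
#' coupled calcium and hydroxyl vacancies, giving the formula
#'
#'   Ca(10-x) (PO4)(6-x) (CO3)x (OH)(2-x)
#'
#' per hexagonal cell (one formula unit).  Charge check: cations
#' 2(10-x) = 20-2x; anions 3(6-x) + 2x + (2-x) = 20-2x.  The model is
#' parameterised either by `x_sub` (formula units of carbonate) or by the
#' carbonate mass fraction in wt%, which is inverted numerically.
#'
#' @param co3_wtpc carbonate mass fraction, wt% (0 to the model maximum of
#'   about 14.6 wt% at x = 2)
#' @return object of class `composition_model`: list with `co3_wtpc`,
#'   `x_sub`, `formula_mass` (g/mol per cell) and `occupancies`, the
#'   expected per-site occupancies implied by the balance (P and its O
#'   sites (6-x)/6, Ca sites (10-x)/10, OH (2-x)/2)
#' @export
#' @examples
#' expected_occupancies(0)$occupancies[["occ_P"]]    # 1
#' expected_occupancies(5.6)$x_sub                   # about 1
expected_occupancies <- function(co3_wtpc) {
  stopifnot(is.numeric(co3_wtpc), length(co3_wtpc) == 1, is.finite(co3_wtpc))
  max_wtpc <- co3_wtpc_from_x(2)
  if (co3_wtpc < 0 || co3_wtpc > max_wtpc)
    stop(sprintf("co3_wtpc must lie in [0, %.3f] for the P-site vacancy model", max_wtpc))
  x <- if (co3_wtpc == 0) 0 else
    uniroot(function(x) co3_wtpc_from_x(x) - co3_wtpc,
            interval = c(0, 2), tol = 1e-12)$root
  composition_from_x(x)
}

#' @rdname expected_occupancies
#' @param x_sub formula units of carbonate substituted per cell, in `[0, 2]`
#' @export
composition_from_x <- function(x_sub) {
  stopifnot(is.numeric(x_sub), length(x_sub) == 1)
  if (x_sub < 0 || x_sub > 2) stop("x_sub must lie in [0, 2]")
  structure(list(
    co3_wtpc = co3_wtpc_from_x(x_sub),
    x_sub = x_sub,
    formula_mass = .formula_mass(x_sub),
    occupancies = c(occ_P = (6 - x_sub) / 6, occ_O1 = (6 - x_sub) / 6,
                    occ_O2 = (6 - x_sub) / 6, occ_O3 = (6 - x_sub) / 6,
                    occ_Ca1 = (10 - x_sub) / 10, occ_Ca2 = (10 - x_sub) / 10,
                    occ_OH = (2 - x_sub) / 2)),
    class = "composition_model")
}

# molar masses of the formula groups
.group_mass <- function() {
  m <- setNames(.species_table$mass, .species_table$species)
  list(Ca = m[["Ca"]],
       PO4 = m[["P"]] + 4 * m[["O"]],
       CO3 = m[["C"]] + 3 * m[["O"]],
       OH = m[["O"]] + m[["H"]])
}

.formula_mass <- function(x) {
  g <- .group_mass()
  (10 - x) * g$Ca + (6 - x) * g$PO4 + x * g$CO3 + (2 - x) * g$OH
}

#' Carbonate mass fraction implied by a substitution level
#'
#' Forward direction of the charge-balance model: wt% CO3 of the formula
#' Ca(10-x)(PO4)(6-x)(CO3)x(OH)(2-x).
#'
#' @param x_sub formula units of carbonate per cell
#' @return carbonate mass fraction, wt%
#' @export
co3_wtpc_from_x <- function(x_sub) {
  g <- .group_mass()
  100 * x_sub * g$CO3 / .formula_mass(x_sub)
}

#' @export
print.composition_model <- function(x, ...) {
  cat(sprintf("carbonate substitution: %.3f wt%% CO3, x = %.4f, M = %.2f g/mol\n",
              x$co3_wtpc, x$x_sub, x$formula_mass))
  cat(sprintf("  expected occupancies: P %.4f, Ca %.4f, OH %.4f\n",
              x$occupancies[["occ_P"]], x$occupancies[["occ_Ca1"]],
              x$occupancies[["occ_OH"]]))
  invisible(x)
}

#' Crystallographic mass density
#'
#' Density from composition and lattice parameters: the formula mass per
#' cell divided by Avogadro's number times the cell volume.  When no
#' composition model is given, the occupancy-weighted mass of the
#' structure's own sites is used instead (this omits the carbonate mass,
#' which is not an explicit site of the model).
#'
#' @param structure a `p1_structure` (provides the cell, and the site
#'   masses in the structure-only mode)
#' @param composition optional [expected_occupancies()] result providing
#'   the formula mass including carbonate
#' @return density, g/cm^3
#' @export
#' @examples
#' hap_density(hydroxyapatite_structure(), expected_occupancies(0))  # ~3.15
hap_density <- function(structure, composition = NULL) {
  v <- cell_volume(structure$cell)
  if (v <= 0) stop("cell volume must be positive")
  mass <- if (is.null(composition)) {
    sum(structure$sites$occ * species_mass(structure$sites$species))
  } else {
    stopifnot(inherits(composition, "composition_model"))
    composition$formula_mass
  }
  mass / (.N_A * v * 1e-24)
}
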