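#' Construct a unit cell
#'
#' Lengths are in angstroms, angles in degrees.  The hexagonal constructor
#' [hexagonal_cell()] enforces the apatite metric constraints `b = a`,
#' `alpha = beta = 90`, `gamma = 120` and is what the apatite model uses;
#' the general constructor exists for cubic reference phases (silicon) and
#' for round-tripping CIF files.
#'
#' @param a,b,c cell edge lengths, angstrom
#' @param alpha,beta,gamma cell angles, degrees
#' @return object of class `unit_cell` with fields `a`, `b`, `c`, `alpha`,
#'   `beta`, `gamma`
#' @export
#' @examples
#' hexagonal_cell(9.4227, 6.8886)
#' cubic_cell(5.4312)
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (a <= 0 || b <= 0 || c <= 0) stop("cell edges must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  if (cell_volume(cell) <= 0) stop("cell volume must be positive")
  cell
}

#' @rdname unit_cell
#' @export
hexagonal_cell <- function(a, c) {
  unit_cell(a, a, c, alpha = 90, beta = 90, gamma = 120)
}

#' @rdname unit_cell
#' @export
cubic_cell <- function(a) unit_cell(a, a, a)

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a = %.4f  b = %.4f  c = %.4f A, angles %g/%g/%g deg, V = %.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Lattice matrix of a cell
#'
#' Returns the 3x3 matrix whose columns are the Cartesian lattice vectors,
#' so that `cart = L %*% frac`.  Standard crystallographic setting: `a`
#' along x, `b` in the xy plane.
#'
#' @param cell a [unit_cell()]
#' @return 3x3 numeric matrix (angstrom)
#' @export
lattice_matrix <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r); cg <- cos(cell$gamma * d2r)
  sg <- sin(cell$gamma * d2r)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg),
         nrow = 3)
}

#' Cell volume in cubic angstroms
#' @param cell a [unit_cell()]
#' @export
cell_volume <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r); cg <- cos(cell$gamma * d2r)
  cell$a * cell$b * cell$c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Convert fractional coordinates to Cartesian
#'
#' @param cell a [unit_cell()]
#' @param frac numeric vector of length 3 or an n x 3 matrix of fractional
#'   coordinates
#' @return Cartesian coordinates in angstrom, same shape as `frac`
#' @export
frac_to_cart <- function(cell, frac) {
  L <- lattice_matrix(cell)
  if (is.matrix(frac)) t(L %*% t(frac)) else as.numeric(L %*% frac)
}

#' @rdname frac_to_cart
#' @param cart Cartesian coordinates, vector of length 3 or n x 3 matrix
#' @export
cart_to_frac <- function(cell, cart) {
  Li <- solve(lattice_matrix(cell))
  if (is.matrix(cart)) t(Li %*% t(cart)) else as.numeric(Li %*% cart)
}

#' Reduce fractional coordinates into [0, 1)
#' @param frac fractional coordinates (vector or matrix)
#' @export
wrap_frac <- function(frac) {
  w <- frac - floor(frac)
  # guard against 0.9999999999 -> 1 after floating subtraction
  w[w >= 1 - 1e-12] <- 0
  w
}

#' Minimum-image distance between two fractional positions
#'
#' Distances are computed under periodic boundary conditions with the cell
#' metric; used for overlap diagnostics, not for the pair sum (which tiles
#' images explicitly).
#'
#' @param cell a [unit_cell()]
#' @param f1,f2 fractional coordinate vectors
#' @export
pbc_distance <- function(cell, f1, f2) {
  d <- f2 - f1
  d <- d - round(d)
  # search neighbouring images: for very oblique cells round() alone is not
  # the true minimum image
  L <- lattice_matrix(cell)
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dd <- sweep(sh, 2, d, "+")
  min(sqrt(rowSums((dd %*% t(L))^2)))
}
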