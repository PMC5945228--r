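#' Crystal unit cell
#'
#' Constructs a unit-cell object holding the cell parameters together with
#' the orthogonalization (fractional -> Cartesian) and fractionalization
#' (Cartesian -> fractional) transforms. The standard PDB convention is
#' used: the a axis lies along Cartesian x and b lies in the x-y plane.
#'
#' @param a,b,c Cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `xtal_cell` with fields `a,b,c,alpha,beta,
#'   gamma`, `orth` (3x3 orthogonalization matrix) and `frac` (its inverse).
#' @examples
#' cell <- crystal_cell(50, 60, 70, 90, 90, 90)
#' orthogonalize(cell, c(0.5, 0.5, 0.5))
#' @export
crystal_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0))
    stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 0) stop("degenerate cell: angles are geometrically inconsistent")
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * sqrt(v) / sg
  ), nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 orth = orth, frac = solve(orth)),
            class = "xtal_cell")
}

#' @export
print.xtal_cell <- function(x, ...) {
  cat(sprintf("<xtal_cell> a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Convert fractional coordinates to Cartesian Angstrom
#'
#' @param cell An `xtal_cell`.
#' @param x A length-3 vector or an N x 3 matrix of fractional coordinates.
#' @return Coordinates in Cartesian Angstrom, same shape as `x`.
#' @export
orthogonalize <- function(cell, x) .cell_apply(cell$orth, x)

#' Convert Cartesian Angstrom coordinates to fractional
#'
#' @inheritParams orthogonalize
#' @param x A length-3 vector or an N x 3 matrix of Cartesian coordinates.
#' @return Fractional coordinates, same shape as `x`.
#' @export
fractionalize <- function(cell, x) .cell_apply(cell$frac, x)

.cell_apply <- function(m, x) {
  if (is.matrix(x)) {
    t(m %*% t(x))
  } else {
    as.numeric(m %*% x)
  }
}
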