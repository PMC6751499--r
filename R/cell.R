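#' Crystallographic unit cell
#'
#' Constructs a validated unit cell from edge lengths and angles.
#'
#' @param a,b,c Cell edge lengths in Angstrom. Must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, strictly between 0 and 180.
#' @return An object of class `unit_cell`: a list with fields `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`.
#' @examples
#' unit_cell(10, 20, 30)
#' unit_cell(78.4, 78.4, 37.1, 90, 90, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  lens <- c(a, b, c)
  angs <- c(alpha, beta, gamma)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("invalid cell: edge lengths must be positive finite numbers")
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180))
    stop("invalid cell: angles must lie strictly between 0 and 180 degrees")
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
    class = "unit_cell"
  )
  # metric tensor determinant > 0 <=> the cell is geometrically realizable
  if (.cell_volume_factor(cell) <= 0)
    stop("invalid cell: angle combination gives a non-positive metric determinant")
  cell
}

# sqrt(1 - ca^2 - cb^2 - cg^2 + 2 ca cb cg); V = a b c * this
.cell_volume_factor <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  s2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (s2 <= 0) return(0)
  sqrt(s2)
}

#' Unit cell volume
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  cell$a * cell$b * cell$c * .cell_volume_factor(cell)
}

#' Fractional/Cartesian transformation for a unit cell
#'
#' Builds the standard crystallographic orthogonalization matrix (a along x,
#' b in the xy-plane) and its inverse.
#'
#' @param cell A [unit_cell()].
#' @return An object of class `cell_transform` with fields `orth` (3x3,
#'   fractional to Cartesian Angstrom) and `deorth` (its inverse).
#' @examples
#' ct <- cell_transform(unit_cell(10, 10, 10))
#' ct$orth %*% c(0.5, 0.5, 0.5)  # (5, 5, 5)
#' @export
cell_transform <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- .cell_volume_factor(cell)
  if (v <= 0) stop("invalid cell: degenerate metric")
  orth <- matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           cell$c * v / sg
  ), nrow = 3, byrow = TRUE)
  structure(list(orth = orth, deorth = solve(orth)), class = "cell_transform")
}

#' Convert fractional to Cartesian coordinates
#'
#' @param ct A [cell_transform()].
#' @param frac Numeric vector of length 3, or a 3-row matrix of columns.
#' @return Cartesian coordinates in the same shape.
#' @export
frac_to_cart <- function(ct, frac) {
  stopifnot(inherits(ct, "cell_transform"))
  drop(ct$orth %*% frac)
}

#' Convert Cartesian to fractional coordinates
#'
#' @param ct A [cell_transform()].
#' @param cart Numeric vector of length 3, or a 3-row matrix of columns.
#' @return Fractional coordinates in the same shape.
#' @export
cart_to_frac <- function(ct, cart) {
  stopifnot(inherits(ct, "cell_transform"))
  drop(ct$deorth %*% cart)
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  (V=%.1f A^3)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}
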