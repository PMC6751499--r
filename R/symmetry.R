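#' Crystallographic symmetry operator
#'
#' An operator in the Cartesian convention used by REMARK 290 SMTRY records:
#' a 3x3 rotation matrix plus a translation vector in Angstrom, applied as
#' `rotation %*% x + translation`.
#'
#' @param rotation 3x3 numeric matrix with |det| = 1 (within 1e-6).
#' @param translation Numeric vector of length 3, Angstrom.
#' @return An object of class `sym_op`.
#' @export
sym_op <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (abs(abs(det(rotation)) - 1) > 1e-6)
    stop("symmetry operator rotation must have |det| = 1")
  structure(list(rotation = rotation, translation = translation),
            class = "sym_op")
}

#' Identity symmetry operator
#' @return A `sym_op` with identity rotation and zero translation.
#' @export
identity_op <- function() sym_op(diag(3), c(0, 0, 0))

#' Test whether an operator is the identity
#' @param op A [sym_op()].
#' @param tol Numeric tolerance.
#' @return Logical.
#' @export
is_identity_op <- function(op, tol = 1e-8) {
  max(abs(op$rotation - diag(3))) <= tol && max(abs(op$translation)) <= tol
}

#' Apply a symmetry operator to a point
#'
#' @param op A [sym_op()].
#' @param point Cartesian coordinates: length-3 vector or 3-row matrix of
#'   column points.
#' @return Transformed coordinates, same shape as `point`.
#' @examples
#' two_fold <- sym_op(diag(c(-1, -1, 1)), c(0, 0, 5))
#' apply_sym_op(two_fold, c(1, 1, 0))  # (-1, -1, 5)
#' @export
apply_sym_op <- function(op, point) {
  stopifnot(inherits(op, "sym_op"))
  if (is.matrix(point)) {
    op$rotation %*% point + op$translation
  } else {
    drop(op$rotation %*% point) + op$translation
  }
}

#' Nearest crystallographic symmetry contact
#'
#' Finds the closest symmetry-related image of any atom of the entry to a
#' given point, searching all symmetry operators combined with lattice
#' translations in `[-shells, +shells]^3`. The image of the model under the
#' identity operator with zero lattice shift (the deposited asymmetric unit
#' itself) is never a contact. Used for the symmetry-exclusion criterion:
#' a metal fails if any symmetry atom lies within 3.5 Angstrom.
#'
#' @param entry A [structure_entry] as returned by [parse_pdb_entry()].
#' @param center Cartesian point (length 3), Angstrom.
#' @param radius Search radius in Angstrom; only contacts at distance
#'   `<= radius` are returned.
#' @param shells Integer: lattice translations searched in
#'   `[-shells, shells]` per axis. By default 1 (the 27 neighboring cells),
#'   auto-escalated when the cell is small relative to the radius.
#' @return A list of class `symmetry_contact` with fields `atom_index`,
#'   `operator_index`, `lattice_shift`, `position`, `distance`; or `NULL`
#'   if no symmetry atom lies within `radius`.
#' @export
nearest_symmetry_contact <- function(entry, center, radius = 3.5,
                                     shells = NULL) {
  stopifnot(inherits(entry, "structure_entry"))
  center <- as.numeric(center)
  stopifnot(length(center) == 3, radius > 0)
  cell <- entry$cell
  min_edge <- min(cell$a, cell$b, cell$c)
  needed <- max(1L, as.integer(ceiling((radius + 2) / min_edge)))
  if (is.null(shells)) {
    shells <- needed
  } else {
    shells <- as.integer(shells)
    if (shells < 1) stop("shells must be >= 1")
    if (shells < needed)
      stop(sprintf(
        "shells = %d cannot cover radius %.2f A for this cell (need >= %d)",
        shells, radius, needed))
  }

  atoms <- entry$atoms
  if (nrow(atoms) == 0) return(NULL)
  X <- t(as.matrix(atoms[, c("x", "y", "z")]))  # 3 x n
  ct <- cell_transform(cell)

  rng <- -shells:shells
  shifts <- as.matrix(expand.grid(sx = rng, sy = rng, sz = rng))
  shift_cart <- ct$orth %*% t(shifts)           # 3 x nshift

  best <- list(d2 = Inf)
  for (k in seq_along(entry$operators)) {
    op <- entry$operators[[k]]
    ident <- is_identity_op(op)
    Y <- apply_sym_op(op, X)                    # 3 x n
    for (s in seq_len(ncol(shift_cart))) {
      if (ident && all(shifts[s, ] == 0)) next
      d <- Y + shift_cart[, s] - center
      d2 <- colSums(d * d)
      i <- which.min(d2)
      if (d2[i] < best$d2) {
        best <- list(d2 = d2[i], atom = i, op = k,
                     shift = as.integer(shifts[s, ]),
                     pos = Y[, i] + shift_cart[, s])
      }
    }
  }
  if (!is.finite(best$d2) || sqrt(best$d2) > radius) return(NULL)
  structure(list(
    atom_index = best$atom,
    operator_index = best$op,
    lattice_shift = best$shift,
    position = as.numeric(best$pos),
    distance = sqrt(best$d2)
  ), class = "symmetry_contact")
}

#' @export
print.symmetry_contact <- function(x, ...) {
  cat(sprintf(
    "Symmetry contact: atom #%d via operator %d, shift (%d,%d,%d), distance %.3f A\n",
    x$atom_index, x$operator_index,
    x$lattice_shift[1], x$lattice_shift[2], x$lattice_shift[3], x$distance))
  invisible(x)
}
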