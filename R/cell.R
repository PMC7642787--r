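## Unit-cell geometry: metric tensor, orthogonalization, reciprocal basis,
## fractional <-> Cartesian transforms and the CIF <-> Cartesian ADP
## convention.  Fractional coordinates are used for crystal bookkeeping,
## Cartesian angstrom for densities and grids; every conversion is explicit.

#' Construct a unit cell
#'
#' @param a,b,c cell lengths in angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return an object of class `unit_cell` with precomputed metric tensor
#'   `g`, orthogonalization matrix `ortho` (Cartesian = ortho %*% fractional),
#'   its inverse `frac`, reciprocal cell lengths `recip` (a*, b*, c*), the
#'   reciprocal-basis matrix `recip_basis` (columns a*, b*, c* vectors) and
#'   the cell volume in angstrom^3.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  ar <- alpha * pi / 180; br <- beta * pi / 180; gr <- gamma * pi / 180
  ca <- cos(ar); cb <- cos(br); cg <- cos(gr); sg <- sin(gr)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("degenerate unit cell (non-positive metric determinant)")
  v <- sqrt(v2)
  vol <- a * b * c * v

  ortho <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * v / sg), nrow = 3, byrow = TRUE)
  frac <- solve(ortho)

  g <- matrix(c(
    a * a,      a * b * cg, a * c * cb,
    a * b * cg, b * b,      b * c * ca,
    a * c * cb, b * c * ca, c * c), nrow = 3, byrow = TRUE)

  recip <- c(b * c * sin(ar), a * c * sin(br), a * b * sg) / vol
  ## reciprocal basis vectors as columns: B = (A^-1)^T so that
  ## (B %*% hkl) . r_cart = hkl . r_frac
  recip_basis <- t(frac)

  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 g = g, ortho = ortho, frac = frac,
                 recip = recip, recip_basis = recip_basis,
                 volume = vol),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional to Cartesian coordinates
#'
#' @param cell a `unit_cell`.
#' @param xyz numeric matrix (n x 3) or length-3 vector of fractional
#'   coordinates.
#' @return matrix (n x 3) of Cartesian coordinates in angstrom.
#' @export
frac_to_cart <- function(cell, xyz) {
  xyz <- rbind3(xyz)
  t(cell$ortho %*% t(xyz))
}

#' Cartesian to fractional coordinates
#' @inheritParams frac_to_cart
#' @param xyz numeric matrix (n x 3) or vector, Cartesian angstrom.
#' @return matrix (n x 3) of fractional coordinates.
#' @export
cart_to_frac <- function(cell, xyz) {
  xyz <- rbind3(xyz)
  t(cell$frac %*% t(xyz))
}

## coerce a length-3 vector or n x 3 matrix to matrix form
rbind3 <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3)
    matrix(x, nrow = 1)
  } else {
    stopifnot(ncol(x) == 3)
    as.matrix(x)
  }
}

#' Reciprocal-space vector of Miller indices
#'
#' @param cell a `unit_cell`.
#' @param hkl integer matrix (n x 3) or length-3 vector.
#' @return matrix (n x 3): Cartesian reciprocal vectors (1/angstrom) such that
#'   `h_cart . r_cart = hkl . r_frac`.
#' @export
hkl_to_cart <- function(cell, hkl) {
  hkl <- rbind3(hkl)
  t(cell$recip_basis %*% t(hkl))
}

#' Resolution (d-spacing) of reflections
#' @inheritParams hkl_to_cart
#' @return numeric vector of d-spacings in angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  h <- hkl_to_cart(cell, hkl)
  1 / sqrt(rowSums(h * h))
}

#' Convert a CIF-convention ADP tensor to Cartesian
#'
#' CIF `U_ij` values refer to the crystallographic axes scaled by the
#' reciprocal cell lengths: `U_cart = A S U_cif S A^T` with `A` the
#' orthogonalization matrix and `S = diag(a*, b*, c*)`.
#'
#' @param u_cif symmetric 3x3 matrix (angstrom^2, CIF convention).
#' @param cell a `unit_cell`.
#' @return symmetric 3x3 Cartesian ADP tensor (angstrom^2).
#' @export
u_cif_to_cartesian <- function(u_cif, cell) {
  stopifnot(is.matrix(u_cif), all(dim(u_cif) == c(3, 3)))
  if (max(abs(u_cif - t(u_cif))) > 1e-10) stop("u_cif must be symmetric")
  as_ <- cell$ortho %*% diag(cell$recip)
  u <- as_ %*% u_cif %*% t(as_)
  (u + t(u)) / 2
}

#' Convert a Cartesian ADP tensor to the CIF convention
#' @param u_cart symmetric 3x3 Cartesian ADP tensor (angstrom^2).
#' @param cell a `unit_cell`.
#' @return symmetric 3x3 matrix in CIF convention.
#' @export
u_cartesian_to_cif <- function(u_cart, cell) {
  stopifnot(is.matrix(u_cart), all(dim(u_cart) == c(3, 3)))
  inv <- solve(cell$ortho %*% diag(cell$recip))
  u <- inv %*% u_cart %*% t(inv)
  (u + t(u)) / 2
}

#' Isotropic-equivalent U value of a CIF ADP tensor
#' @param u_cif 3x3 CIF-convention tensor.
#' @param cell a `unit_cell`.
#' @return scalar U_eq = trace(U_cart)/3 (angstrom^2).
#' @export
u_equiv <- function(u_cif, cell) {
  sum(diag(u_cif_to_cartesian(u_cif, cell))) / 3
}

#' Isotropic U as a CIF tensor
#'
#' Builds the CIF-convention tensor whose Cartesian image is `u_iso * I`.
#' @param u_iso scalar isotropic displacement (angstrom^2).
#' @param cell a `unit_cell`.
#' @return 3x3 matrix in CIF convention.
#' @export
u_iso_to_cif <- function(u_iso, cell) {
  u_cartesian_to_cif(diag(rep(u_iso, 3)), cell)
}
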