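## Physical constants and per-element tables used across the package.
## All internal lengths are in angstrom, charges in e, dipoles in e*A.

#' @keywords internal
BOHR_ANGSTROM <- 0.52917721

## atomic-unit dipole in e*A (1 a.u. dipole = e * bohr)
AU_DIPOLE_EA <- BOHR_ANGSTROM

.ELEMENTS <- c("H", "C", "N", "O", "P", "S")

.ATOMIC_NUMBER <- c(H = 1L, C = 6L, N = 7L, O = 8L, P = 15L, S = 16L)

## Bragg-Slater radii (A); H set to 0.35 A, the usual choice for
## Becke cell-size adjustment of hydrogen.
.BRAGG_SLATER <- c(H = 0.35, C = 0.70, N = 0.65, O = 0.60, P = 1.00, S = 1.00)

## Covalent radii (A) for bond detection (whole-molecule connectivity).
.COVALENT_RADIUS <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05)

## Default per-element dipole polarizabilities (A^3-scale fixture constants,
## order-of-magnitude realism only; configurable per model).
.POLARIZABILITY <- c(H = 0.4, C = 1.8, N = 1.1, O = 0.8, P = 3.6, S = 2.9)

#' Atomic number of a supported element
#'
#' @param element character vector of element symbols.
#' @return integer vector of atomic numbers.
#' @export
atomic_number <- function(element) {
  z <- .ATOMIC_NUMBER[element]
  if (anyNA(z)) {
    bad <- unique(element[is.na(z)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(.ELEMENTS, collapse = ", "))
  }
  unname(z)
}

#' Bragg-Slater radius (angstrom)
#' @param element character vector of element symbols.
#' @return numeric vector of radii in angstrom.
#' @export
bragg_slater_radius <- function(element) {
  r <- .BRAGG_SLATER[element]
  if (anyNA(r)) stop("no Bragg-Slater radius for: ",
                     paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Covalent radius (angstrom)
#' @param element character vector of element symbols.
#' @return numeric vector of radii in angstrom.
#' @export
covalent_radius <- function(element) {
  r <- .COVALENT_RADIUS[element]
  if (anyNA(r)) stop("no covalent radius for: ",
                     paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Default scalar dipole polarizability (angstrom^3 scale)
#' @param element character vector of element symbols.
#' @return numeric vector.
#' @export
default_polarizability <- function(element) {
  a <- .POLARIZABILITY[element]
  if (anyNA(a)) stop("no polarizability entry for: ",
                     paste(unique(element[is.na(a)]), collapse = ", "))
  unname(a)
}
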