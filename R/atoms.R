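## Analytic spherical atomic densities: minimal Slater expansions
## rho(r) = sum_i N_i zeta_i^3/(8 pi) exp(-zeta_i r), normalised so each
## shell integrates exactly to N_i electrons.  These replace quantum-
## mechanically computed isolated-atom densities; the exponents are shipped
## constants derived from screened single-zeta orbital exponents (density
## exponent = 2 x orbital exponent, converted from 1/bohr to 1/angstrom),
## which is enough structure for exercising stockholder partitions.

## shells: list per element of rbind(population, zeta[1/A]) for the neutral
## atom.  One shell for H, two for C/N/O (core + valence), three for P/S.
.SLATER_NEUTRAL <- list(
  H = cbind(c(1, 3.77946)),
  C = cbind(c(2, 21.4418), c(4, 6.04713)),
  N = cbind(c(2, 25.1912), c(5, 7.25656)),
  O = cbind(c(2, 28.9444), c(6, 8.50426)),
  P = cbind(c(2, 55.0255), c(8, 17.0085), c(5, 6.04713)),
  S = cbind(c(2, 58.7287), c(8, 18.8973), c(6, 6.80302))
)

## charge states shipped: -1..+1 for H,C,N,O; 0 only for P,S.
.ION_STATES <- list(H = -1:1, C = -1:1, N = -1:1, O = -1:1, P = 0L, S = 0L)

## ions modify the valence shell: population -+1 and a contraction/expansion
## of the valence exponent (cations tighter, anions more diffuse).
.ION_ZETA_SCALE <- c(`-1` = 0.85, `0` = 1, `1` = 1.15)

#' Spherical atomic density of a shipped species
#'
#' @param element one of H, C, N, O, P, S.
#' @param charge_state integer ionic charge (-1, 0, +1 where shipped).
#' @return an `atom_density` object: `element`, `charge_state`, `shells`
#'   (2 x k matrix: populations and exponents in 1/angstrom) and
#'   `n_electrons`.
#' @export
builtin_atom_table <- function(element, charge_state = 0L) {
  if (!element %in% names(.SLATER_NEUTRAL))
    stop("no atomic density for element '", element, "'; available: ",
         paste(names(.SLATER_NEUTRAL), collapse = ", "))
  charge_state <- as.integer(charge_state)
  if (!charge_state %in% .ION_STATES[[element]])
    stop("no shipped density for ", element, " charge ", charge_state,
         "; available charge states: ",
         paste(.ION_STATES[[element]], collapse = ", "))
  shells <- .SLATER_NEUTRAL[[element]]
  k <- ncol(shells)
  shells[1, k] <- shells[1, k] - charge_state
  shells[2, k] <- shells[2, k] * .ION_ZETA_SCALE[[as.character(charge_state)]]
  structure(list(element = element, charge_state = charge_state,
                 shells = shells,
                 n_electrons = sum(shells[1, ])),
            class = "atom_density")
}

#' @export
print.atom_density <- function(x, ...) {
  cat(sprintf("atom density %s (charge %+d): %d shell(s), %g electrons\n",
              x$element, x$charge_state, ncol(x$shells), x$n_electrons))
  invisible(x)
}

#' Evaluate a spherical atomic density
#'
#' @param atom an `atom_density` from [builtin_atom_table()], or an
#'   arbitrary 2 x k shells matrix.
#' @param r numeric vector of radial distances (angstrom).
#' @return density values in e/angstrom^3.
#' @export
atom_density_at <- function(atom, r) {
  shells <- if (inherits(atom, "atom_density")) atom$shells else atom
  out <- numeric(length(r))
  for (i in seq_len(ncol(shells))) {
    n <- shells[1, i]; z <- shells[2, i]
    if (n == 0) next
    out <- out + n * z^3 / (8 * pi) * exp(-z * r)
  }
  out
}

#' Interpolated species density for iterative Hirshfeld
#'
#' Builds the stockholder weight-function density for a fractional
#' population by linear interpolation (in population) between the two
#' shipped integer-electron species bracketing it.
#'
#' @param element element symbol.
#' @param population fractional electron population.
#' @param r radial distances (angstrom).
#' @return density values (e/angstrom^3).
#' @export
interpolated_species_density <- function(element, population, r) {
  z <- atomic_number(element)
  states <- .ION_STATES[[element]]
  pops <- z - states  # electron counts of the shipped species
  lo <- min(pops); hi <- max(pops)
  if (population < lo - 1e-9 || population > hi + 1e-9)
    stop("population ", signif(population, 6), " for ", element,
         " outside shipped charge-state bracket [", lo, ", ", hi, "]")
  population <- min(max(population, lo), hi)
  below <- max(pops[pops <= population + 1e-12])
  above <- min(pops[pops >= population - 1e-12])
  d_lo <- atom_density_at(builtin_atom_table(element, z - below), r)
  if (above == below) return(d_lo)
  d_hi <- atom_density_at(builtin_atom_table(element, z - above), r)
  f <- (population - below) / (above - below)
  (1 - f) * d_lo + f * d_hi
}
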