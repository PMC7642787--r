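## Synthetic molecular electron density: a promolecule of analytic Slater
## atoms plus polarizable atom-centred dipolar deformation terms.  This
## model stands in for a quantum-mechanical density so that partitioning,
## form factors and refinement can be exercised end to end; its deformation
## terms carry exactly zero charge and a prescribed dipole moment.

#' Promolecule density
#'
#' Superposition of spherical neutral-atom densities at the molecular
#' geometry; the denominator of the stockholder partition when the weights
#' are isolated-atom densities.
#'
#' @param molecule a molecule (list with `elements`, `cart`) or
#'   [crystal_structure()].
#' @param points m x 3 matrix of Cartesian points (angstrom).
#' @return density values in e/angstrom^3 (strictly positive).
#' @export
promolecule_density <- function(molecule, points) {
  mol <- as_molecule(molecule)
  points <- rbind3(points)
  out <- numeric(nrow(points))
  for (a in seq_along(mol$elements)) {
    dx <- sweep(points, 2, mol$cart[a, ])
    r <- sqrt(rowSums(dx * dx))
    out <- out + atom_density_at(builtin_atom_table(mol$elements[a]), r)
  }
  out
}

## dipolar deformation radial profile g(s) = s zeta^4/(8 pi) exp(-zeta s);
## the full term -(zeta/4) (d . u) g(s) integrates to zero charge and to a
## physical (electrons-negative) dipole moment d.  The deformation exponent
## is tied to the atom's outermost shell but contracted (factor 1.75) so the
## deformation always decays faster than the spherical tail and moderate
## dipoles keep the total density positive.
.deformation_zeta <- function(element) {
  shells <- .SLATER_NEUTRAL[[element]]
  1.75 * shells[2, ncol(shells)]
}

#' Construct a polarizable molecular density model
#'
#' @param molecule molecule or [crystal_structure()].
#' @param deformation_dipoles n x 3 matrix of per-atom dipole moments
#'   (e angstrom, physical sign: electrons negative); defaults to zero.
#' @param polarizability per-atom scalar polarizabilities (angstrom^3
#'   scale); defaults to the shipped per-element table.
#' @return a `density_model`.
#' @export
molecular_density_model <- function(molecule, deformation_dipoles = NULL,
                                    polarizability = NULL) {
  mol <- as_molecule(molecule)
  n <- length(mol$elements)
  if (is.null(deformation_dipoles)) deformation_dipoles <- matrix(0, n, 3)
  deformation_dipoles <- rbind3(deformation_dipoles)
  stopifnot(nrow(deformation_dipoles) == n)
  if (is.null(polarizability)) polarizability <- default_polarizability(mol$elements)
  stopifnot(length(polarizability) == n)
  structure(list(molecule = mol,
                 static_dipoles = deformation_dipoles,
                 dipoles = deformation_dipoles,
                 polarizability = polarizability,
                 zeta_def = vapply(mol$elements, .deformation_zeta, numeric(1)),
                 n_electrons = sum(vapply(mol$elements, function(e)
                   builtin_atom_table(e)$n_electrons, numeric(1)))),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("density model: %d atom(s), %g electrons, max |dipole| %.4g e A\n",
              length(x$molecule$elements), x$n_electrons,
              if (nrow(x$dipoles)) max(sqrt(rowSums(x$dipoles^2))) else 0))
  invisible(x)
}

#' Evaluate a polarized molecular density
#'
#' Promolecule plus atom-centred dipolar deformation terms
#' `-(zeta_d/4) (d_a . u) g(|r - R_a|)`; each term integrates to zero
#' charge and carries the physical dipole `d_a`.
#'
#' @param model a `density_model`.
#' @param points m x 3 Cartesian points (angstrom).
#' @param check_positive error when the model density is negative at any
#'   requested point (the linear response is being pushed too far).
#' @return density values (e/angstrom^3).
#' @export
polarized_density <- function(model, points, check_positive = TRUE) {
  stopifnot(inherits(model, "density_model"))
  points <- rbind3(points)
  rho <- promolecule_density(model$molecule, points)
  for (a in seq_along(model$molecule$elements)) {
    d <- model$dipoles[a, ]
    if (all(d == 0)) next
    dx <- sweep(points, 2, model$molecule$cart[a, ])
    s <- sqrt(rowSums(dx * dx))
    s <- pmax(s, 1e-14)
    du <- (dx %*% d)[, 1] / s          # (d . u)
    z <- model$zeta_def[a]
    g <- s * z^4 / (8 * pi) * exp(-z * s)
    rho <- rho - (z / 4) * du * g
  }
  if (check_positive && any(rho < 0))
    stop("polarized density negative at ", sum(rho < 0),
         " point(s); field too strong for the linear deformation model")
  rho
}

#' Set deformation dipoles from an electric field
#'
#' Linear response on top of any permanent (static) deformation:
#' `d_a = d_a^static + alpha_a E(R_a)`.
#'
#' @param model a `density_model`.
#' @param field n x 3 matrix of electric-field vectors at the atomic
#'   centres (e/angstrom^2).
#' @return the model with updated dipoles.
#' @export
polarize_model <- function(model, field) {
  field <- rbind3(field)
  stopifnot(nrow(field) == nrow(model$dipoles))
  model$dipoles <- model$static_dipoles + field * model$polarizability
  model
}

#' Density values of a model on a molecular grid
#'
#' @param model a `density_model` (or a molecule, treated as an unpolarized
#'   promolecule).
#' @param grid a `molecular_grid`.
#' @return numeric vector of densities at the grid points.
#' @export
density_on_grid <- function(model, grid) {
  if (inherits(model, "density_model"))
    polarized_density(model, grid$points)
  else promolecule_density(model, grid$points)
}
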