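## Synthetic crystals and diffraction data with known ground truth: a
## urea-like 8-atom planar molecule (or an O-H diatomic) in a small P1 or
## P-1 cell, and simulated intensities on an enumerated reflection list
## with an optional Gaussian sigma-model noise.

## planar urea-like molecule (Cartesian angstrom, xy plane):
## C=O 1.26 A, C-N 1.34 A, N-H ~1.0 A
.UREA_LIKE <- list(
  elements = c("C", "O", "N", "N", "H", "H", "H", "H"),
  labels = c("C1", "O1", "N1", "N2", "H11", "H12", "H21", "H22"),
  cart = rbind(
    c( 0.000,  0.000, 0),
    c( 0.000,  1.260, 0),
    c( 1.160, -0.670, 0),
    c(-1.160, -0.670, 0),
    c( 1.990, -0.130, 0),
    c( 1.180, -1.680, 0),
    c(-1.990, -0.130, 0),
    c(-1.180, -1.680, 0)),
  ## true Cartesian ADPs (angstrom^2): modest anisotropy, hydrogens larger
  u_cart = list(
    diag(c(0.010, 0.012, 0.014)),
    matrix(c(0.016, 0.002, 0, 0.002, 0.012, 0, 0, 0, 0.018), 3, 3),
    matrix(c(0.013, -0.002, 0, -0.002, 0.015, 0, 0, 0, 0.016), 3, 3),
    matrix(c(0.013, 0.002, 0, 0.002, 0.015, 0, 0, 0, 0.016), 3, 3),
    diag(c(0.030, 0.026, 0.032)),
    diag(c(0.028, 0.024, 0.034)),
    diag(c(0.030, 0.026, 0.032)),
    diag(c(0.028, 0.024, 0.034))))

.DIATOMIC <- list(
  elements = c("O", "H"),
  labels = c("O1", "H1"),
  cart = rbind(c(0, 0, 0), c(0.97, 0, 0)),
  u_cart = list(diag(c(0.012, 0.014, 0.013)), diag(c(0.025, 0.030, 0.028))))

#' Specification of a synthetic crystal
#'
#' @param template `"urea_like"`, `"diatomic"`, or `"custom"` (supply `xyz`).
#' @param symmetry `"P1"` or `"P-1"`.
#' @param d_min resolution limit for simulated data (angstrom).
#' @param noise_c fractional-intensity noise coefficient `c` in
#'   `sigma(h) = max(sigma_floor, c |F|^2)`.
#' @param sigma_floor noise floor on the F^2 scale.
#' @param polarize logical: should the ground-truth density carry the
#'   self-consistently embedded deformation dipoles?
#' @param seed integer seed controlling every random draw.
#' @param xyz for `template = "custom"`: list with `elements`, `cart`,
#'   optionally `labels` and `u_cart`.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(template = c("urea_like", "diatomic", "custom"),
                           symmetry = c("P-1", "P1"), d_min = 0.8,
                           noise_c = 0.02, sigma_floor = 0.5,
                           polarize = FALSE, seed = 1L, xyz = NULL) {
  template <- match.arg(template)
  symmetry <- match.arg(symmetry)
  if (d_min <= 0) stop("d_min must be positive")
  structure(list(template = template, symmetry = symmetry, d_min = d_min,
                 noise_c = noise_c, sigma_floor = sigma_floor,
                 polarize = polarize, seed = as.integer(seed), xyz = xyz),
            class = "synthetic_spec")
}

#' Build the synthetic crystal of a specification
#'
#' The urea-like template is an 8-atom planar molecule in a small
#' orthorhombic (tetragonal-like) cell reduced to P1 or P-1; ground truth
#' (positions, ADPs, polarization flag) is returned alongside and is
#' independent of the emitted CIF.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `structure` (a [crystal_structure()]) and `truth`
#'   (list: `frac`, `u_cif` per site, `labels`, `polarize`, `spec`).
#' @export
make_crystal <- function(spec) {
  tpl <- switch(spec$template,
                urea_like = .UREA_LIKE,
                diatomic = .DIATOMIC,
                custom = {
                  if (is.null(spec$xyz)) stop("custom template needs xyz")
                  x <- spec$xyz
                  atomic_number(x$elements)  # validates elements
                  if (is.null(x$labels))
                    x$labels <- paste0(x$elements, seq_along(x$elements))
                  if (is.null(x$u_cart))
                    x$u_cart <- replicate(length(x$elements),
                                          diag(0.02, 3), simplify = FALSE)
                  x
                })
  cell <- switch(spec$template,
                 urea_like = unit_cell(6.0, 5.4, 4.6),
                 diatomic = unit_cell(5.5, 4.5, 4.2),
                 custom = {
                   span <- apply(rbind3(tpl$cart), 2, function(v)
                     diff(range(v)))
                   do.call(unit_cell, as.list(span + 4.5))
                 })
  center_frac <- if (spec$symmetry == "P1") c(0.5, 0.5, 0.5)
                 else c(0.25, 0.30, 0.25)
  symops <- if (spec$symmetry == "P1") "x,y,z" else c("x,y,z", "-x,-y,-z")
  cart <- rbind3(tpl$cart)
  com <- colMeans(cart)
  frac <- sweep(cart_to_frac(cell, sweep(cart, 2, com)), 2, center_frac, "+")
  sites <- lapply(seq_along(tpl$elements), function(a)
    atom_site(tpl$labels[a], tpl$elements[a], frac[a, ],
              u_cartesian_to_cif(tpl$u_cart[[a]], cell)))
  structure_ <- crystal_structure(cell, sites, symops)
  list(structure = structure_,
       truth = list(frac = frac,
                    u_cif = lapply(sites, `[[`, "u_cif"),
                    labels = tpl$labels, polarize = spec$polarize,
                    spec = spec))
}

#' Enumerate unique reflections to a resolution limit
#'
#' One hemisphere of reciprocal space (Friedel mates carry no extra
#' information for real scattering densities), excluding 000.
#'
#' @param cell a `unit_cell`.
#' @param d_min resolution limit (angstrom).
#' @return integer matrix (n x 3) of Miller indices.
#' @export
enumerate_hkl <- function(cell, d_min) {
  hmax <- floor(c(cell$a, cell$b, cell$c) / d_min)
  gr <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                              l = 0:hmax[3]))
  keep <- gr[, 3] > 0 | (gr[, 3] == 0 & gr[, 2] > 0) |
    (gr[, 3] == 0 & gr[, 2] == 0 & gr[, 1] > 0)
  gr <- gr[keep, , drop = FALSE]
  d <- d_spacing(cell, gr)
  gr <- gr[d >= d_min, , drop = FALSE]
  dimnames(gr) <- NULL
  gr
}

## grid specification used for production simulation/refinement runs;
## dense enough that shipped-atom form factors are converged well below the
## noise level while keeping desk-scale runtimes
production_grid_spec <- function() grid_spec(n_radial = c(H = 48, C = 56, N = 56, O = 56, P = 64, S = 64),
                                             max_angular = 578)

#' Simulate a reflection set from a density model
#'
#' Computes structure factors through the full pipeline (molecular grid at
#' the true geometry, Hirshfeld partition of the model density, aspherical
#' form factors, Debye-Waller smearing, symmetry sum) and adds optional
#' Gaussian noise with `sigma(h) = max(sigma_floor, c |F|^2)`.  Negative
#' noisy intensities are retained: refinement is against F^2.
#'
#' @param structure a [crystal_structure()] at the true geometry.
#' @param model a `density_model` for the asymmetric unit (the ground-truth
#'   density).
#' @param d_min resolution limit (angstrom).
#' @param noise `"none"` or `"gaussian"`.
#' @param seed integer seed for the noise draws.
#' @param noise_c,sigma_floor noise-model parameters.
#' @param grid optional prebuilt `molecular_grid`; built from
#'   `grid_spec_sim` when missing.
#' @param grid_spec_sim grid specification for the simulation.
#' @param scheme partition used for the atom-wise split entering the
#'   Debye-Waller convolution (the total F is split-independent only for
#'   identical ADPs); Hirshfeld by default.
#' @return a [reflection_set()].
#' @export
simulate_reflections <- function(structure, model, d_min = 0.8,
                                 noise = c("gaussian", "none"), seed = 1L,
                                 noise_c = 0.02, sigma_floor = 0.5,
                                 grid = NULL,
                                 grid_spec_sim = production_grid_spec(),
                                 scheme = "hirshfeld") {
  noise <- match.arg(noise)
  hkl <- enumerate_hkl(structure$cell, d_min)
  if (is.null(grid)) grid <- build_molecular_grid(structure, grid_spec_sim)
  rho <- density_on_grid(model, grid)
  part <- partition_density(scheme, rho, grid)
  fft <- form_factor_table(structure, part, grid, hkl)
  F <- structure_factors(structure, fft)
  f2 <- abs(F)^2
  sig <- pmax(sigma_floor, noise_c * f2)
  if (noise == "gaussian") {
    set.seed(seed)
    f2 <- f2 + stats::rnorm(length(f2), 0, sig)
  }
  reflection_set(hkl, f2, sig, cell = structure$cell)
}

#' Oscillation-provoking refinement fixture
#'
#' A diatomic crystal whose density model couples the hydrogen's dipolar
#' deformation linearly to its displacement from the reference geometry
#' (`d_H = kappa * dx_H`), an exaggerated caricature of the
#' geometry-following bond polarization that makes the outer
#' refine/recompute loop of aspherical-atom refinements overshoot.  For
#' sufficiently strong coupling the undamped outer loop reverses direction
#' every cycle and diverges; two-cycle averaging restores convergence.
#'
#' @param kappa coupling strength (e angstrom per angstrom displacement).
#' @param displacement starting hydrogen displacement (angstrom).
#' @param d_min resolution of the simulated noise-free data (angstrom).
#' @return list with `structure` (displaced start), `reflections`
#'   (noise-free), `truth` (reference geometry record), `model_fn` (to be
#'   passed to [gar_settings()]) and `kappa`.
#' @export
oscillation_fixture <- function(kappa = -0.8, displacement = 0.02,
                                d_min = 0.9) {
  cr <- make_crystal(synthetic_spec("diatomic", d_min = d_min))
  ref_frac <- cr$truth$frac
  cell <- cr$structure$cell
  model_fn <- function(structure) {
    st <- site_table(structure)
    dx <- frac_to_cart(cell, st$frac[2, ] - ref_frac[2, ])[1, ]
    dip <- rbind(c(0, 0, 0), kappa * dx)
    molecular_density_model(structure, deformation_dipoles = dip)
  }
  refl <- simulate_reflections(cr$structure, model_fn(cr$structure),
                               d_min = d_min, noise = "none")
  start <- cr$structure
  start$sites[[2]]$frac_pos <- start$sites[[2]]$frac_pos +
    cart_to_frac(cell, c(displacement, 0, 0))[1, ]
  list(structure = start, reflections = refl, truth = cr$truth,
       model_fn = model_fn, kappa = kappa)
}
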