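# Shared fixtures, built lazily and cached for the whole test run.
# Grids here are deliberately compact: partitions and form factors are
# grid-agnostic properties, so the tests use node counts well below the
# production defaults wherever the asserted tolerance allows it.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# compact grid for partition/scatter unit tests
tiny_spec <- function() grid_spec(n_radial = 40, max_angular = 288)

# O-H molecule with a polarized (aspherical) density
oh_fixture <- function() fixture("oh", function() {
  mol <- list(elements = c("O", "H"), cart = rbind(c(0, 0, 0), c(0.97, 0, 0)))
  grid <- build_molecular_grid(mol, tiny_spec())
  model <- molecular_density_model(
    mol, deformation_dipoles = rbind(c(-0.08, 0, 0), c(0.1, 0, 0)))
  rho <- polarized_density(model, grid$points)
  list(mol = mol, grid = grid, model = model, rho = rho,
       n_electrons = 9)
})

# symmetric H2 molecule (denser angular rung: its tests assert 1e-6-level
# quadrature identities, which need the off-centre cusp resolved)
h2_fixture <- function() fixture("h2", function() {
  mol <- list(elements = c("H", "H"),
              cart = rbind(c(0, 0, -0.37), c(0, 0, 0.37)))
  grid <- build_molecular_grid(mol, grid_spec(n_radial = 48,
                                              max_angular = 578))
  rho <- promolecule_density(mol, grid$points)
  list(mol = mol, grid = grid, rho = rho)
})

# urea-like synthetic crystal (P-1) and its promolecule on a compact grid
urea_fixture <- function() fixture("urea", function() {
  cr <- make_crystal(synthetic_spec("urea_like"))
  grid <- build_molecular_grid(cr$structure, tiny_spec())
  rho <- promolecule_density(cr$structure, grid$points)
  list(crystal = cr, grid = grid, rho = rho, n_electrons = 32)
})

# the same crystal on the production grid (refinement-quality quadrature)
urea_prod_fixture <- function() fixture("urea_prod", function() {
  cr <- make_crystal(synthetic_spec("urea_like"))
  grid <- build_molecular_grid(cr$structure, production_grid_spec())
  rho <- promolecule_density(cr$structure, grid$points)
  list(crystal = cr, grid = grid, rho = rho, n_electrons = 32)
})

# the same crystal on the full default grid, for 1e-6-level quadrature checks
urea_default_fixture <- function() fixture("urea_default", function() {
  cr <- make_crystal(synthetic_spec("urea_like"))
  grid <- build_molecular_grid(cr$structure)
  rho <- promolecule_density(cr$structure, grid$points)
  list(crystal = cr, grid = grid, rho = rho, n_electrons = 32)
})

# noise-free diatomic dataset for refinement tests
diatomic_data <- function() fixture("diatomic_data", function() {
  cr <- make_crystal(synthetic_spec("diatomic"))
  model <- molecular_density_model(cr$structure)
  refl <- simulate_reflections(cr$structure, model, d_min = 0.9,
                               noise = "none")
  grid <- build_molecular_grid(cr$structure, production_grid_spec())
  rho <- density_on_grid(model, grid)
  part <- hirshfeld(rho, grid)
  fft <- form_factor_table(cr$structure, part, grid, refl$hkl)
  list(crystal = cr, model = model, refl = refl, grid = grid,
       part = part, fft = fft)
})

# random SPD 3x3 ADP-like tensor on the 0.01 A^2 scale
random_spd <- function() {
  m <- matrix(rnorm(9, sd = 0.05), 3, 3)
  s <- crossprod(m) + diag(0.01, 3)
  s * 0.2
}
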