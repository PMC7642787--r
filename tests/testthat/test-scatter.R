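# Form factors, Debye-Waller smearing, structure factors, the multipole
# cluster and the self-consistent embedding.

test_that("f(0) equals the partitioned electron population", {
  fx <- oh_fixture()
  p <- hirshfeld(fx$rho, fx$grid)
  for (a in 1:2) {
    f0 <- atomic_form_factor(atomic_density(p, a), fx$grid,
                             fx$mol$cart[a, ], c(0, 0, 0))
    expect_equal(Re(f0), p$populations[a], tolerance = 1e-6)
    expect_equal(Im(f0), 0, tolerance = 1e-10)
  }
})

test_that("Gaussian and Slater transforms match their closed forms", {
  h1 <- list(elements = "H", cart = matrix(0, 1, 3))
  g <- build_molecular_grid(h1, grid_spec(n_radial = 120,
                                          max_angular = 1682),
                            prune = FALSE)
  r2 <- rowSums(g$points^2)
  hv <- cbind(c(0.3, 0.5, 1 / (2 * pi)), 0, 0)
  f_g <- atomic_form_factor(2 * (1 / pi)^1.5 * exp(-r2), g, c(0, 0, 0), hv)
  expect_equal(Re(f_g), 2 * exp(-pi^2 * hv[, 1]^2), tolerance = 1e-5)
  f_s <- atomic_form_factor(2^3 / (8 * pi) * exp(-2 * sqrt(r2)), g,
                            c(0, 0, 0), hv)
  expect_equal(Re(f_s), 1 / (1 + (2 * pi * hv[, 1] / 2)^2)^2,
               tolerance = 1e-4)
  # the worked value at |h| = 1/(2 pi): 1/(1 + 1/4)^2 = 0.64
  expect_equal(Re(f_s[3]), 0.64, tolerance = 1e-4)
})

test_that("Debye-Waller factor follows exp(-2 pi^2 h U h)", {
  expect_equal(debye_waller(matrix(0, 3, 3), c(1, 0, 0)), 1)
  expect_equal(debye_waller(diag(0.01, 3), c(1, 0, 0)),
               exp(-0.02 * pi^2), tolerance = 1e-14)
  u <- random_spd()
  h <- c(0.3, -0.5, 0.7)
  expect_equal(debye_waller(u, h), debye_waller(u, -h))
})

test_that("structure factors: single site, Friedel pairs, centrosymmetry", {
  fx <- urea_fixture()
  cr <- fx$crystal$structure
  p <- hirshfeld(fx$rho, fx$grid)
  hkl <- rbind(c(1, 2, 0), c(0, 2, 1), c(2, -1, 1))
  fft <- form_factor_table(cr, p, fx$grid, rbind(hkl, -hkl))
  F <- structure_factors(cr, fft, scale = 1.0)
  # P-1 with real form factors: F real
  expect_lt(max(abs(Im(F))) / max(abs(F)), 1e-10)
  # Friedel symmetry
  expect_equal(F[1:3], Conj(F[4:6]), tolerance = 1e-12)

  # single atom at the origin in P1: F = K f T
  cell <- unit_cell(8, 8, 8)
  s1 <- crystal_structure(cell, list(
    atom_site("O1", "O", c(0, 0, 0), u_iso_to_cif(0.015, cell))))
  mol1 <- list(elements = "O", cart = matrix(0, 1, 3))
  g1 <- build_molecular_grid(mol1, tiny_spec())
  p1 <- hirshfeld(promolecule_density(mol1, g1$points), g1)
  h1 <- rbind(c(2, 1, 0))
  fft1 <- form_factor_table(s1, p1, g1, h1)
  F1 <- structure_factors(s1, fft1, scale = 1.7)
  hc <- hkl_to_cart(cell, h1)
  expected <- 1.7 * fft1$f[[1]][1, 1] *
    debye_waller(u_cif_to_cartesian(u_iso_to_cif(0.015, cell), cell), hc)
  expect_equal(F1[1], expected, tolerance = 1e-10)
})

test_that("structure factors match a semi-analytic independent oracle", {
  # For a promolecule density the Hirshfeld atoms are exactly the isolated
  # spherical atoms, whose transform is a closed-form sum over Slater
  # shells; assembling F from that analytic path shares nothing with the
  # grid form-factor machinery.
  fx <- urea_prod_fixture()
  cr <- fx$crystal$structure
  p <- hirshfeld(fx$rho, fx$grid)
  hkl <- enumerate_hkl(cr$cell, 0.9)
  set.seed(2); hkl <- hkl[sample(nrow(hkl), 40), ]
  fft <- form_factor_table(cr, p, fx$grid, hkl)
  F_pkg <- structure_factors(cr, fft)

  st <- site_table(cr)
  F_ref <- complex(nrow(hkl))
  for (op in cr$symops) {
    hkl_rot <- hkl %*% op$R
    hc <- hkl_to_cart(cr$cell, hkl_rot)
    habs <- sqrt(rowSums(hc^2))
    for (a in seq_along(cr$sites)) {
      at <- builtin_atom_table(st$elements[a])
      f_analytic <- numeric(nrow(hkl))
      for (i in seq_len(ncol(at$shells))) {
        N <- at$shells[1, i]; z <- at$shells[2, i]
        f_analytic <- f_analytic + N / (1 + (2 * pi * habs / z)^2)^2
      }
      u_cart <- u_cif_to_cartesian(cr$sites[[a]]$u_cif, cr$cell)
      Tf <- exp(-2 * pi^2 * rowSums((hc %*% u_cart) * hc))
      ph <- 2 * pi * (as.numeric(hkl_rot %*% st$frac[a, ]) +
                      as.numeric(hkl %*% op$t))
      F_ref <- F_ref + f_analytic * Tf * exp(1i * ph)
    }
  }
  expect_lt(max(abs(abs(F_pkg) - abs(F_ref)) / pmax(abs(F_ref), 1)), 1e-3)
})

test_that("partitioned form factors sum to the molecular transform", {
  fx <- oh_fixture()
  p <- iterative_hirshfeld(fx$rho, fx$grid)
  hv <- rbind(c(0.2, 0.1, 0), c(0.5, -0.3, 0.2))
  # sum_a f_a(h) phase-referenced to the common origin
  total <- 0
  for (a in 1:2) {
    fa <- atomic_form_factor(atomic_density(p, a), fx$grid,
                             fx$mol$cart[a, ], hv, drop_tol = 0)
    total <- total + fa * exp(2i * pi * as.numeric(hv %*% fx$mol$cart[a, ]))
  }
  direct <- vapply(1:2, function(i)
    sum(fx$grid$w * fx$rho *
          exp(2i * pi * as.numeric(fx$grid$points %*% hv[i, ]))),
    complex(1))
  expect_lt(max(abs(total - direct) / abs(direct)), 1e-10)
})

test_that("cluster enumeration matches brute force and respects the cutoff", {
  cr <- make_crystal(synthetic_spec("diatomic"))
  st <- site_table(cr$structure)
  q <- c(-0.2, 0.2)
  # tiny cutoff below the closest intermolecular contact: empty
  cl0 <- build_cluster(cr$structure, q, cutoff = 1.0)
  expect_equal(cl0$n_molecules, 0L)
  expect_error(build_cluster(cr$structure, q, cutoff = -1), "cutoff")

  cl8 <- build_cluster(cr$structure, q, cutoff = 8)
  # brute-force enumeration over symmetry images and translations
  count <- 0
  for (k in seq_along(cr$structure$symops)) {
    op <- cr$structure$symops[[k]]
    for (t1 in -3:3) for (t2 in -3:3) for (t3 in -3:3) {
      if (k == 1 && t1 == 0 && t2 == 0 && t3 == 0) next
      fr <- t(op$R %*% t(st$frac)) +
        matrix(op$t + c(t1, t2, t3), 2, 3, byrow = TRUE)
      ct <- frac_to_cart(cr$structure$cell, fr)
      hit <- FALSE
      for (a in 1:2) for (b in 1:2)
        if (sqrt(sum((ct[a, ] - st$cart[b, ])^2)) <= 8) hit <- TRUE
      if (hit) count <- count + 1
    }
  }
  expect_equal(cl8$n_molecules, count)
  # charges only: one point charge per image atom
  expect_equal(length(cl8$charge_q), 2 * count)
})

test_that("dipoles are represented as split charge pairs", {
  cr <- make_crystal(synthetic_spec("diatomic"))
  mu <- rbind(c(0, 0, 0), c(0.05, 0, 0))
  cl <- build_cluster(cr$structure, c(0, 0), dipoles = mu, cutoff = 5,
                      dipole_split = 0.02)
  ## each image contributes 2 monopoles (zero charges kept) + 1 charge pair
  expect_equal(length(cl$charge_q) %% cl$n_molecules, 0)
  qp <- cl$charge_q[abs(cl$charge_q) > 1e-9]
  expect_equal(length(qp), 2 * cl$n_molecules)
  expect_equal(unique(round(abs(qp), 9)), 0.05 / 0.02)
  expect_equal(sum(cl$charge_q), 0, tolerance = 1e-12)
})

test_that("self-consistent embedding reaches and verifies its fixed point", {
  cr <- make_crystal(synthetic_spec("diatomic"))
  grid <- build_molecular_grid(cr$structure, tiny_spec())
  model <- molecular_density_model(
    cr$structure, deformation_dipoles = rbind(c(-0.05, 0, 0), c(0.08, 0, 0)))

  emb <- self_consistent_embedding(cr$structure, model, grid, cutoff = 6)
  expect_true(emb$converged)
  expect_lt(tail(emb$history, 1), 0.003)
  # one clean re-evaluation pass reproduces the multipoles within tol
  rho <- polarized_density(emb$model, grid$points)
  mp <- atomic_multipoles(hirshfeld(rho, grid), grid)
  expect_lt(max(abs(mp$charges - emb$charges)), 0.003)
  expect_lt(max(abs(mp$dipoles - emb$dipoles)) / 0.52917721, 0.003)

  # zero polarizability: converged after a single pass
  m0 <- molecular_density_model(cr$structure,
                                deformation_dipoles = model$static_dipoles,
                                polarizability = c(0, 0))
  emb0 <- self_consistent_embedding(cr$structure, m0, grid, cutoff = 6)
  expect_equal(emb0$iterations, 1L)
  expect_true(emb0$converged)

  # an isolated molecule (empty cluster) leaves the density unchanged
  embi <- self_consistent_embedding(cr$structure, model, grid, cutoff = 0.5)
  expect_equal(embi$cluster$n_molecules, 0L)
  expect_equal(embi$model$dipoles, model$static_dipoles)
})
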