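# File I/O and coordinate/ADP conventions.

test_that("unit cell transforms round-trip and behave on orthogonal cells", {
  cl <- unit_cell(10, 11, 12, 80, 95, 100)
  set.seed(42)
  x <- matrix(runif(30), 10, 3)
  expect_lt(max(abs(cart_to_frac(cl, frac_to_cart(cl, x)) - x)), 1e-12)
  expect_gt(cl$volume, 0)
  expect_lt(max(abs(cl$g - t(cl$g))), 1e-12)
  expect_true(all(eigen(cl$g, symmetric = TRUE)$values > 0))
})

test_that("CIF convention ADP transform matches an independent construction", {
  # orthorhombic: CIF and Cartesian tensors coincide for diagonal U
  ortho <- unit_cell(5, 7, 9)
  u <- diag(c(0.01, 0.02, 0.03))
  expect_equal(u_cif_to_cartesian(u, ortho), u, tolerance = 1e-12)
  # unit cube: identity
  cube <- unit_cell(1, 1, 1)
  expect_equal(u_cif_to_cartesian(u, cube), u, tolerance = 1e-12)

  # triclinic: compare against brute-force transform assembled from explicit
  # basis vectors (independent of the package's orthogonalization matrix)
  tric <- unit_cell(10, 11, 12, 80, 95, 100)
  u_iso <- diag(0.015, 3)
  deg <- pi / 180
  ca <- cos(80 * deg); cb <- cos(95 * deg); cg <- cos(100 * deg)
  avec <- 10 * c(1, 0, 0)
  bvec <- 11 * c(cg, sin(100 * deg), 0)
  cx <- cb; cy <- (ca - cb * cg) / sin(100 * deg)
  cvec <- 12 * c(cx, cy, sqrt(1 - cx^2 - cy^2))
  M <- rbind(avec, bvec, cvec)              # rows are direct basis vectors
  Mi <- solve(M)                            # columns are reciprocal vectors
  astar <- sqrt(colSums(Mi^2))              # reciprocal lengths
  A_s <- t(M) %*% diag(astar)
  u_ref <- A_s %*% u_iso %*% t(A_s)
  u_pkg <- u_cif_to_cartesian(u_iso, tric)
  expect_equal(sum(diag(u_pkg)), sum(diag(u_ref)), tolerance = 1e-10)
  expect_equal(u_pkg, (u_ref + t(u_ref)) / 2, tolerance = 1e-10)
})

test_that("ADP transform preserves positive definiteness on random cells", {
  set.seed(7)
  for (i in 1:20) {
    cl <- unit_cell(runif(1, 4, 12), runif(1, 4, 12), runif(1, 4, 12),
                    runif(1, 70, 110), runif(1, 70, 110), runif(1, 70, 110))
    u <- random_spd()
    uc <- u_cif_to_cartesian(u, cl)
    expect_true(all(eigen(uc, symmetric = TRUE)$values > 0))
    expect_equal(u_cartesian_to_cif(uc, cl), u, tolerance = 1e-10)
  }
})

test_that("minimal CIF parses: single atom, P1, aniso copied verbatim", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_min",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.1 0.2 0.3",
    "loop_", "_atom_site_aniso_label",
    "_atom_site_aniso_U_11", "_atom_site_aniso_U_22", "_atom_site_aniso_U_33",
    "_atom_site_aniso_U_23", "_atom_site_aniso_U_13", "_atom_site_aniso_U_12",
    "C1 0.02 0.03 0.04 0.001 0.002 0.003"), path)
  s <- read_cif(path)
  expect_length(s$sites, 1)
  expect_length(s$symops, 1)
  expect_equal(s$sites[[1]]$u_cif[1, 1], 0.02)
  expect_equal(s$sites[[1]]$u_cif[2, 3], 0.001)
  expect_equal(s$sites[[1]]$frac_pos, c(0.1, 0.2, 0.3))
})

test_that("CIF errors and warnings follow the contract", {
  p1 <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site_label", "_atom_site_fract_x",
               "_atom_site_fract_y", "_atom_site_fract_z", "C1 0 0 0"), p1)
  expect_error(read_cif(p1), "cell")

  p2 <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell_length_a 10", "_cell_length_b 10",
               "_cell_length_c 10",
               "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y",
               "_atom_site_fract_z", "Q9 Xx 0 0 0"), p2)
  expect_error(read_cif(p2), "Q9")

  p3 <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell_length_a 10", "_cell_length_b 10",
               "_cell_length_c 10",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y",
               "_atom_site_fract_z", "C1 C 0 0 0"), p3)
  expect_warning(s <- read_cif(p3), "P1")
  expect_length(s$symops, 1)
})

test_that("synthetic CIF round-trips to 1e-10 in all numeric fields", {
  cr <- make_crystal(synthetic_spec("urea_like"))
  path <- withr::local_tempfile(fileext = ".cif")
  write_cif(cr$structure, path)
  s2 <- read_cif(path)
  expect_equal(s2$cell$a, cr$structure$cell$a, tolerance = 1e-12)
  for (a in seq_along(cr$structure$sites)) {
    expect_equal(s2$sites[[a]]$frac_pos, cr$structure$sites[[a]]$frac_pos,
                 tolerance = 1e-10)
    expect_equal(s2$sites[[a]]$u_cif, cr$structure$sites[[a]]$u_cif,
                 tolerance = 1e-10)
    expect_identical(s2$sites[[a]]$label, cr$structure$sites[[a]]$label)
  }
  expect_length(s2$symops, 2)  # P-1
})

test_that("HKLF-4 lines parse by fixed-width fields", {
  path <- withr::local_tempfile(fileext = ".hkl")
  writeLines(c("   1   0   0   123.4     5.6",
               "   0   0   0    0.00    0.00"), path)
  r <- read_hkl(path)
  expect_equal(nrow(r$hkl), 1)
  expect_equal(r$hkl[1, ], c(1L, 0L, 0L))
  expect_equal(r$f_obs_sq, 123.4)
  expect_equal(r$sigma, 5.6)
})

test_that("duplicate reflections merge by weighted mean", {
  path <- withr::local_tempfile(fileext = ".hkl")
  writeLines(c("   1   2   3  100.00    4.00",
               "   1   2   3  110.00    4.00",
               "   2   0   0   50.00    2.00"), path)
  r <- read_hkl(path)
  expect_equal(nrow(r$hkl), 2)
  i <- which(r$hkl[, 1] == 1)
  expect_equal(r$f_obs_sq[i], 105)          # arithmetic mean, equal sigma
  expect_equal(r$sigma[i], 4 / sqrt(2))
})

test_that("hkl write/read round-trips at format precision", {
  cr <- make_crystal(synthetic_spec("diatomic"))
  set.seed(3)
  hkl <- unique(matrix(sample(-4:4, 60, replace = TRUE), ncol = 3))
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  refl <- reflection_set(hkl, runif(nrow(hkl), 1, 900),
                         runif(nrow(hkl), 0.5, 5), cell = cr$structure$cell)
  path <- withr::local_tempfile(fileext = ".hkl")
  write_hkl(refl, path)
  r2 <- read_hkl(path, cell = cr$structure$cell)
  m <- match(paste(refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3]),
             paste(r2$hkl[, 1], r2$hkl[, 2], r2$hkl[, 3]))
  expect_false(anyNA(m))
  expect_lt(max(abs(r2$f_obs_sq[m] - refl$f_obs_sq)), 5.1e-3)
  expect_lt(max(abs(r2$sigma[m] - refl$sigma)), 5.1e-3)
})

test_that("malformed and unusable reflections are handled", {
  path <- withr::local_tempfile(fileext = ".hkl")
  writeLines(c("   1   0   0   100.0     1.0", "garbage line here"), path)
  expect_error(read_hkl(path), "line 2")

  p2 <- withr::local_tempfile(fileext = ".hkl")
  writeLines(c("   1   0   0   100.0     1.0",
               "   2   0   0   100.0    -1.0"), p2)
  r <- read_hkl(p2)
  expect_equal(r$usable, c(TRUE, FALSE))
  expect_equal(nrow(r$hkl), 2)              # retained, flagged
})

test_that("XYZ files round-trip", {
  path <- withr::local_tempfile(fileext = ".xyz")
  el <- c("C", "O", "H")
  xyz <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(-0.5, 0.9, 0.1))
  write_xyz(el, xyz, path, comment = "test")
  m <- read_xyz(path)
  expect_identical(m$elements, el)
  expect_equal(m$cart, xyz, tolerance = 1e-9)
})
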