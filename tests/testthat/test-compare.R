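# Neutron-benchmark comparison statistics.

# helper: cubic P1 structure with labelled atoms at given Cartesian sites
.toy_structure <- function(labels, elements, cart, u = NULL, a = 12) {
  cell <- unit_cell(a, a, a)
  sites <- lapply(seq_along(labels), function(i)
    atom_site(labels[i], elements[i], cart_to_frac(cell, cart[i, ])[1, ],
              if (is.null(u)) diag(0.02, 3) else u[[i]]))
  crystal_structure(cell, sites)
}

test_that("population SD uses the n convention", {
  expect_equal(population_sd(c(1, 2, 3)), sqrt(2 / 3))
  expect_equal(population_sd(rep(5, 4)), 0)
})

test_that("identical structures give null bond statistics", {
  s <- .toy_structure(c("A1", "A2"), c("O", "H"),
                      rbind(c(0, 0, 0), c(1, 0, 0)))
  bs <- bond_stats(s, s, cbind("A1", "A2"), sigma_x = 1e-3)
  expect_equal(bs$mean_dr, 0)
  expect_equal(bs$wrmsd, 0)
  expect_equal(bs$mean_ratio, 1)
})

test_that("the unity-wRMSD worked example holds", {
  # two bonds with dR = {+3, -4} mA and sigma(dR) = {3, 4} mA
  sx <- .toy_structure(c("A1", "A2", "B1", "B2"), c("N", "H", "N", "H"),
                       rbind(c(0, 0, 0), c(1.003, 0, 0),
                             c(0, 4, 0), c(0.996, 4, 0)))
  sn <- .toy_structure(c("A1", "A2", "B1", "B2"), c("N", "H", "N", "H"),
                       rbind(c(0, 0, 0), c(1.000, 0, 0),
                             c(0, 4, 0), c(1.000, 4, 0)))
  bs <- bond_stats(sx, sn, rbind(c("A1", "A2"), c("B1", "B2")),
                   sigma_x = c(3e-3, 4e-3), sigma_n = 0)
  expect_equal(bs$bonds$dr_mA, c(3, -4), tolerance = 1e-9)
  expect_equal(bs$wrmsd, 1, tolerance = 1e-9)
  # the {1,2,3} mA example: <dR> = 2, <|dR|> = 2, SD = sqrt(2/3)
  sx3 <- .toy_structure(paste0("C", 1:6), rep(c("C", "H"), 3),
                        rbind(c(0, 0, 0), c(1.001, 0, 0),
                              c(0, 4, 0), c(1.002, 4, 0),
                              c(0, 8, 0), c(1.003, 8, 0)))
  sn3 <- .toy_structure(paste0("C", 1:6), rep(c("C", "H"), 3),
                        rbind(c(0, 0, 0), c(1.000, 0, 0),
                              c(0, 4, 0), c(1.000, 4, 0),
                              c(0, 8, 0), c(1.000, 8, 0)))
  bs3 <- bond_stats(sx3, sn3,
                    rbind(c("C1", "C2"), c("C3", "C4"), c("C5", "C6")),
                    sigma_x = 1e-3)
  expect_equal(bs3$mean_dr, 2, tolerance = 1e-9)
  expect_equal(bs3$mean_abs_dr, 2, tolerance = 1e-9)
  expect_equal(bs3$mean_dr_sd, sqrt(2 / 3), tolerance = 1e-9)
  # label mismatch errors; all-zero sigmas are excluded with a warning
  expect_error(bond_stats(sx3, sn3, rbind(c("C1", "Q9"))), "Q9")
  expect_warning(bond_stats(sx3, sn3, rbind(c("C1", "C2")), sigma_x = 0),
                 "excluded")
})

test_that("ADP discrepancy statistics follow the component arithmetic", {
  u_n <- list(diag(0.02, 3), diag(0.03, 3))
  s_n <- .toy_structure(c("A1", "A2"), c("C", "H"),
                        rbind(c(0, 0, 0), c(1, 0, 0)), u = u_n)
  st_id <- adp_stats(s_n, s_n, sigma_x = 1e-3)
  expect_equal(st_id$mean_abs_du, 0)
  expect_equal(st_id$mean_s12, 0, tolerance = 1e-9)
  expect_equal(st_id$mean_vratio, 1, tolerance = 1e-12)

  # U_X - U_N = 0.005 I: three diagonal components differ, three vanish
  u_x <- lapply(u_n, function(u) u + diag(0.005, 3))
  s_x <- .toy_structure(c("A1", "A2"), c("C", "H"),
                        rbind(c(0, 0, 0), c(1, 0, 0)), u = u_x)
  st <- adp_stats(s_x, s_n, sigma_x = 1e-3)
  expect_equal(st$mean_abs_du, 0.0025, tolerance = 1e-12)
})

test_that("ADP statistics agree with an independent component loop", {
  set.seed(21)
  u_x <- replicate(4, random_spd(), simplify = FALSE)
  u_n <- replicate(4, random_spd(), simplify = FALSE)
  labs <- paste0("X", 1:4)
  cart <- cbind(seq(0, 9, by = 3), 0, 0)
  s_x <- .toy_structure(labs, rep("C", 4), cart, u = u_x)
  s_n <- .toy_structure(labs, rep("C", 4), cart, u = u_n)
  st <- adp_stats(s_x, s_n, sigma_x = 2e-3, sigma_n = 1e-3)
  # brute force over explicit index pairs (cubic cell: CIF == Cartesian)
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  du <- c(); wr <- c()
  for (k in 1:4) for (ij in pairs) {
    d <- u_x[[k]][ij[1], ij[2]] - u_n[[k]][ij[1], ij[2]]
    du <- c(du, abs(d))
    wr <- c(wr, d^2 / (2e-3^2 + 1e-3^2))
  }
  expect_equal(st$mean_abs_du, mean(du), tolerance = 1e-12)
  expect_equal(st$wrmsd, sqrt(mean(wr)), tolerance = 1e-12)
})

test_that("S12 closed form matches its worked value and invariances", {
  u <- random_spd()
  expect_equal(s12(u, u), 0, tolerance = 1e-10)
  # the isotropic worked pair: R12 = 8/(5 sqrt(5))
  v <- s12(diag(0.01, 3), diag(0.04, 3))
  expect_equal(v, 100 * (1 - 8 / (5 * sqrt(5))), tolerance = 1e-10)
  # symmetry and rotation invariance
  set.seed(31)
  u1 <- random_spd(); u2 <- random_spd()
  expect_equal(s12(u1, u2), s12(u2, u1), tolerance = 1e-12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(s12(R %*% u1 %*% t(R), R %*% u2 %*% t(R)), s12(u1, u2),
               tolerance = 1e-10)
  expect_gte(s12(u1, u2), 0)
  expect_error(s12(diag(c(1, 1, -1)) * 0.01, u1), "positive definite")
  # continuity: S12 -> 0 as U2 -> U1
  eps <- c(1e-2, 1e-3, 1e-4)
  vals <- vapply(eps, function(e) s12(u1, u1 + diag(e * 0.01, 3)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("closed-form R12 agrees with direct numerical integration", {
  set.seed(41)
  for (i in 1:5) {
    u1 <- random_spd(); u2 <- random_spd()
    r12_cf <- 1 - s12(u1, u2) / 100
    expect_equal(r12_numeric(u1, u2), r12_cf, tolerance = 1e-4)
  }
})

test_that("volume ratios follow the determinant rule", {
  u <- random_spd()
  expect_equal(volume_ratio(u, u), 1, tolerance = 1e-12)
  expect_equal(volume_ratio(2 * u, u), 2^1.5, tolerance = 1e-12)
  # eigenvalue-product oracle
  set.seed(51)
  u1 <- random_spd(); u2 <- random_spd()
  ev1 <- eigen(u1, symmetric = TRUE, only.values = TRUE)$values
  ev2 <- eigen(u2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(volume_ratio(u1, u2), sqrt(prod(ev1) / prod(ev2)),
               tolerance = 1e-12)
  expect_error(volume_ratio(diag(c(-0.01, 0.01, 0.01)), u1),
               "positive definite")
})

test_that("isotropic neutron-ADP rescaling recovers known scales", {
  set.seed(61)
  u_n <- replicate(10, random_spd(), simplify = FALSE)
  u_x <- lapply(u_n, function(u) 2 * u)
  expect_equal(scale_neutron_adps(u_x, u_n)$k, 2, tolerance = 1e-12)
  expect_equal(scale_neutron_adps(u_n, u_n)$k, 1, tolerance = 1e-12)
  expect_error(scale_neutron_adps(u_x, lapply(u_n, function(u) u * 0)),
               "zero")
  # noisy proportional fixture: k_true = 1.3, component noise 0.001 A^2,
  # tensors on the realistic heavy-atom ADP scale (~0.01-0.05 A^2)
  k_true <- 1.3
  u_n <- lapply(u_n, function(u) 6 * u)
  u_noisy <- lapply(u_n, function(u) {
    e <- matrix(rnorm(9, sd = 0.001), 3, 3)
    k_true * u + (e + t(e)) / 2
  })
  fit <- scale_neutron_adps(u_noisy, u_n)
  expect_lt(abs(fit$k - k_true), 0.02)
  expect_equal(fit$rescaled[[1]], fit$k * u_n[[1]], tolerance = 1e-12)
})
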