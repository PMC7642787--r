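# Least-squares refinement and the GAR outer loop.

test_that("noise-free self-generated data refine back to the generator", {
  d <- diatomic_data()
  res <- lsq_refine(d$crystal$structure, d$refl, d$fft)
  expect_true(res$converged)
  expect_lt(res$wr2, 1e-6)
  truth_cart <- frac_to_cart(d$crystal$structure$cell, d$crystal$truth$frac)
  got_cart <- site_table(res$structure)$cart
  expect_lt(max(sqrt(rowSums((got_cart - truth_cart)^2))), 1e-4)
  for (a in 1:2)
    expect_lt(max(abs(res$structure$sites[[a]]$u_cif -
                      d$crystal$truth$u_cif[[a]])), 1e-5)
})

test_that("scale-only refinement recovers a known scale exactly", {
  d <- diatomic_data()
  scaled <- d$refl
  scaled$f_obs_sq <- 2.5 * scaled$f_obs_sq
  res <- lsq_refine(d$crystal$structure, scaled, d$fft,
                    refine_xyz = FALSE, refine_u = FALSE)
  expect_equal(res$scale, 2.5, tolerance = 1e-8)
})

test_that("weights scale out of the estimates but not the uncertainties", {
  d <- diatomic_data()
  noisy <- d$refl
  set.seed(9)
  noisy$f_obs_sq <- noisy$f_obs_sq + rnorm(length(noisy$f_obs_sq),
                                           sd = noisy$sigma)
  r1 <- lsq_refine(d$crystal$structure, noisy, d$fft, gof_rescale = FALSE)
  doubled <- noisy
  doubled$sigma <- 2 * noisy$sigma
  r2 <- lsq_refine(d$crystal$structure, doubled, d$fft, gof_rescale = FALSE)
  p1 <- vapply(r1$structure$sites, `[[`, numeric(3), "frac_pos")
  p2 <- vapply(r2$structure$sites, `[[`, numeric(3), "frac_pos")
  expect_equal(p1, p2, tolerance = 1e-8)
  expect_equal(r2$sigmas, 2 * r1$sigmas, tolerance = 1e-6)
  # with GooF rescaling the sigma estimates are sigma-scale invariant
  r1g <- lsq_refine(d$crystal$structure, noisy, d$fft, gof_rescale = TRUE)
  r2g <- lsq_refine(d$crystal$structure, doubled, d$fft, gof_rescale = TRUE)
  expect_equal(r2g$sigmas, r1g$sigmas, tolerance = 1e-6)
})

test_that("reported R factors are recomputable from the stored quantities", {
  d <- diatomic_data()
  res <- lsq_refine(d$crystal$structure, d$refl, d$fft)
  use <- d$refl$usable
  y2 <- abs(res$f_calc[use])^2
  wr2 <- sqrt(sum(((d$refl$f_obs_sq[use] - res$scale * y2) /
                     d$refl$sigma[use])^2) /
              sum((d$refl$f_obs_sq[use] / d$refl$sigma[use])^2))
  expect_equal(res$wr2, wr2, tolerance = 1e-12)
  fo <- sqrt(pmax(d$refl$f_obs_sq[use], 0))
  r1 <- sum(abs(fo - sqrt(res$scale) * abs(res$f_calc[use]))) / sum(fo)
  expect_equal(res$r1, r1, tolerance = 1e-12)
  expect_true(all(res$sigmas >= 0))
})

test_that("parameter errors track the data noise level", {
  # with noise at the stated sigma, |error|/sigma_estimate should be O(1)
  d <- diatomic_data()
  truth <- vapply(d$crystal$structure$sites, `[[`, numeric(3), "frac_pos")
  ratios <- c()
  for (seed in 1:6) {
    noisy <- d$refl
    set.seed(seed)
    noisy$f_obs_sq <- noisy$f_obs_sq + rnorm(length(noisy$f_obs_sq),
                                             sd = noisy$sigma)
    r <- lsq_refine(d$crystal$structure, noisy, d$fft)
    est <- vapply(r$structure$sites, `[[`, numeric(3), "frac_pos")
    err <- abs(est - truth)
    sig <- matrix(r$sigmas[grep("\\.(x|y|z)$", names(r$sigmas))], 3)
    ratios <- c(ratios, err / sig)
  }
  expect_gt(median(ratios), 0.25)
  expect_lt(median(ratios), 2.5)
})

test_that("recovery error grows with the noise level", {
  d <- diatomic_data()
  rmse <- vapply(c(0, 0.02, 0.05), function(cc) {
    errs <- vapply(1:3, function(seed) {
      noisy <- d$refl
      sig <- pmax(0.5, cc * noisy$f_obs_sq)
      set.seed(seed)
      noisy$f_obs_sq <- noisy$f_obs_sq + rnorm(length(sig), sd = sig)
      noisy$sigma <- sig
      r <- lsq_refine(d$crystal$structure, noisy, d$fft)
      got <- site_table(r$structure)$cart
      truth <- frac_to_cart(d$crystal$structure$cell, d$crystal$truth$frac)
      sqrt(mean((got - truth)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("GAR starting at the generating geometry stops in one cycle", {
  d <- diatomic_data()
  g <- gar_loop(d$crystal$structure, d$refl,
                gar_settings("hirshfeld", max_outer = 3))
  expect_true(g$converged)
  expect_equal(g$cycles, 1L)
})

test_that("GAR recovers displaced hydrogens on noise-free data", {
  d <- diatomic_data()
  pert <- d$crystal$structure
  pert$sites[[2]]$frac_pos <- pert$sites[[2]]$frac_pos +
    cart_to_frac(pert$cell, c(0.05, 0, 0))[1, ]
  g <- gar_loop(pert, d$refl, gar_settings("hirshfeld", max_outer = 10))
  expect_true(g$converged)
  expect_lte(g$cycles, 10L)
  truth_cart <- frac_to_cart(d$crystal$structure$cell, d$crystal$truth$frac)
  expect_lt(max(sqrt(rowSums((site_table(g$structure)$cart -
                              truth_cart)^2))), 1e-3)
  # trace records the convergence path
  expect_true(all(c("max_dxyz", "max_dbond", "wr2") %in% names(g$trace)))
  expect_lt(tail(g$trace$max_dxyz, 1), 0.001)
})

test_that("partition schemes agree on shared data except the cell scheme", {
  # Data simulated with the Hirshfeld split; the stockholder family
  # converges to the same geometry, while the Becke cells deviate by an
  # order of magnitude more -- the partition artefact itself.
  d <- diatomic_data()
  pert <- d$crystal$structure
  pert$sites[[2]]$frac_pos <- pert$sites[[2]]$frac_pos +
    cart_to_frac(pert$cell, c(0.03, 0, 0))[1, ]
  geom <- list()
  for (s in c("hirshfeld", "mbis", "iterative-hirshfeld", "becke")) {
    g <- gar_loop(pert, d$refl, gar_settings(s, max_outer = 8))
    geom[[s]] <- site_table(g$structure)$cart
  }
  spread_stock <- max(abs(geom$mbis - geom$hirshfeld),
                      abs(geom$`iterative-hirshfeld` - geom$hirshfeld))
  spread_becke <- max(abs(geom$becke - geom$hirshfeld))
  expect_lt(spread_stock, 2e-4)
  expect_gt(spread_becke, spread_stock)
  cat(sprintf("\n  [recorded] geometry spread: stockholder %.2e A, Becke %.2e A\n",
              spread_stock, spread_becke))
})

test_that("the oscillating fixture diverges undamped and converges damped", {
  fx <- oscillation_fixture()
  undamped <- gar_loop(fx$structure, fx$reflections,
                       gar_settings("hirshfeld", damping = "off",
                                    max_outer = 6,
                                    model_fn = fx$model_fn))
  expect_false(undamped$converged)
  # geometry steps alternate in direction and grow
  cosines <- undamped$trace$step_cos[-1]
  expect_true(all(cosines < 0))
  expect_gt(tail(undamped$trace$max_dxyz, 1),
            undamped$trace$max_dxyz[1])

  damped <- gar_loop(fx$structure, fx$reflections,
                     gar_settings("hirshfeld", damping = "auto",
                                  max_outer = 14,
                                  model_fn = fx$model_fn))
  expect_true(damped$converged)
  expect_true(any(damped$trace$damped))
  expect_lt(tail(damped$trace$max_dxyz, 1), 0.001)
})
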