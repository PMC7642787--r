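## Exhaustive partitions of a molecular electron density sampled on a
## multicenter grid into atomic densities: Becke cells, Hirshfeld,
## iterative Hirshfeld, iterative stockholder, and minimal-basis iterative
## stockholder.  Every scheme returns per-atom weight fields w_a(r) with
## sum_a w_a = 1 at each grid point, so sum_a rho_a recovers the molecular
## density exactly wherever the pro-density does not underflow.

.UNDERFLOW_FLOOR <- 1e-30

## distances of every grid point to every atom (n_points x n_atoms)
.point_atom_dist <- function(grid) {
  mol <- grid$molecule
  n <- length(mol$elements)
  d <- matrix(0, nrow(grid$points), n)
  for (a in seq_len(n)) {
    dx <- sweep(grid$points, 2, mol$cart[a, ])
    d[, a] <- sqrt(rowSums(dx * dx))
  }
  d
}

## stockholder weights from per-atom pro-density columns; points where the
## pro-density underflows are assigned to the nearest atom (they carry
## negligible quadrature mass).
.stockholder_weights <- function(pro, dist) {
  tot <- rowSums(pro)
  low <- tot < .UNDERFLOW_FLOOR
  w <- pro / pmax(tot, .UNDERFLOW_FLOOR)
  if (any(low)) {
    w[low, ] <- 0
    nearest <- max.col(-dist[low, , drop = FALSE])
    w[cbind(which(low), nearest)] <- 1
  }
  w
}

.new_partition_result <- function(scheme, weights, rho, grid, iterations,
                                  converged, history, extra = list()) {
  mol <- grid$molecule
  z <- atomic_number(mol$elements)
  pops <- as.numeric(crossprod(weights, grid$w * rho))
  out <- c(list(scheme = scheme, weights = weights, rho = rho,
                populations = pops, charges = z - pops,
                iterations = iterations, converged = converged,
                history = history, molecule = mol),
           extra)
  class(out) <- "partition_result"
  out
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition (%s): %d iteration(s), %s\n", x$scheme,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  cat("  charges:", paste(sprintf("%s %+0.4f", x$molecule$elements,
                                  x$charges), collapse = ", "), "\n")
  invisible(x)
}

#' Per-atom density values of a partition
#' @param result a `partition_result`.
#' @param atom atom index.
#' @return numeric vector: `rho * w_atom` at each grid point.
#' @export
atomic_density <- function(result, atom) {
  result$rho * result$weights[, atom]
}

## ---------------------------------------------------------------------

#' Hirshfeld partition
#'
#' Stockholder weights from isolated neutral-atom densities:
#' `w_a = rho0_a / sum_k rho0_k`.
#'
#' @param rho molecular density values at the grid points (e/angstrom^3).
#' @param grid a `molecular_grid`.
#' @return a `partition_result`.
#' @export
hirshfeld <- function(rho, grid) {
  mol <- grid$molecule
  dist <- .point_atom_dist(grid)
  pro <- matrix(0, nrow(grid$points), length(mol$elements))
  for (a in seq_along(mol$elements))
    pro[, a] <- atom_density_at(builtin_atom_table(mol$elements[a]), dist[, a])
  w <- .stockholder_weights(pro, dist)
  .new_partition_result("hirshfeld", w, rho, grid, 1L, TRUE, numeric(0))
}

#' Becke partition
#'
#' Non-stockholder partition by smoothed Voronoi cells with atomic-size
#' adjustment (the same cell functions used for grid fusion).
#'
#' @inheritParams hirshfeld
#' @return a `partition_result`.
#' @export
becke_partition <- function(rho, grid) {
  mol <- grid$molecule
  w <- becke_cell_weights(mol$cart, bragg_slater_radius(mol$elements),
                          grid$points)
  .new_partition_result("becke", w, rho, grid, 1L, TRUE, numeric(0))
}

#' Iterative Hirshfeld partition
#'
#' Weight functions are population-interpolated combinations of the shipped
#' neutral-atom and ion densities, iterated to the fixed point at which the
#' populations implied by the partition equal the populations used to build
#' the weights.
#'
#' @inheritParams hirshfeld
#' @param tol convergence threshold on the largest population change (e).
#' @param max_iter iteration cap; exceeding it returns an unconverged
#'   result with a warning.
#' @return a `partition_result`; `history` records the largest population
#'   change per iteration.
#' @export
iterative_hirshfeld <- function(rho, grid, tol = 1e-6, max_iter = 500L) {
  mol <- grid$molecule
  n <- length(mol$elements)
  dist <- .point_atom_dist(grid)
  pops <- vapply(mol$elements, function(e)
    builtin_atom_table(e)$n_electrons, numeric(1))
  history <- numeric(0)
  converged <- FALSE
  damping <- FALSE
  prev_delta <- NULL
  w <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pro <- matrix(0, nrow(grid$points), n)
    for (a in seq_len(n))
      pro[, a] <- interpolated_species_density(mol$elements[a], pops[a],
                                               dist[, a])
    w_new <- .stockholder_weights(pro, dist)
    w <- if (damping && !is.null(w)) 0.5 * (w + w_new) else w_new
    new_pops <- as.numeric(crossprod(w, grid$w * rho))
    delta <- new_pops - pops
    history <- c(history, max(abs(delta)))
    ## oscillation detection: sign-alternating changes for 4 iterations
    if (!damping && !is.null(prev_delta) && length(history) >= 4) {
      recent <- utils::tail(history, 4)
      if (all(delta * prev_delta < 0) && all(recent > tol)) damping <- TRUE
    }
    prev_delta <- delta
    pops <- new_pops
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("iterative Hirshfeld did not converge in ", max_iter,
            " iterations (last change ", signif(utils::tail(history, 1), 3), " e)")
  .new_partition_result("iterative-hirshfeld", w, rho, grid, it, converged,
                        history)
}

## spherical average of per-point values about each atom, evaluated on the
## atom's own radial shells (angular-weight average), then log-linearly
## interpolated onto arbitrary distances and clamped at the shell range.
.spherical_average_profile <- function(values, grid, atom) {
  sel <- grid$owner == atom
  idx <- grid$radial_index[sel]
  wa <- grid$w_angular[sel]
  v <- values[sel]
  num <- rowsum(wa * v, idx)
  den <- rowsum(wa, idx)
  avg <- as.numeric(num / den)
  rr <- as.numeric(rowsum(grid$radial_r[sel], idx)) /
    as.numeric(rowsum(rep(1, sum(sel)), idx))
  list(r = rr, avg = pmax(avg, .UNDERFLOW_FLOOR))
}

.eval_profile <- function(profile, r) {
  lr <- log(pmax(profile$avg, .UNDERFLOW_FLOOR))
  r_cl <- pmin(pmax(r, profile$r[1]), profile$r[length(profile$r)])
  exp(stats::approx(profile$r, lr, xout = r_cl, rule = 2)$y)
}

#' Iterative stockholder partition
#'
#' Starts from uniform weight functions (`w_k = 1` for all atoms) and
#' repeatedly replaces each atom's weight function by the spherical average
#' of its current atomic density about its nucleus, evaluated on the atom's
#' own radial shells.
#'
#' @inheritParams iterative_hirshfeld
#' @return a `partition_result`; `history` holds the largest population
#'   change per iteration and `profiles` the converged radial weight
#'   profiles.
#' @export
iterative_stockholder <- function(rho, grid, tol = 1e-6, max_iter = 500L) {
  mol <- grid$molecule
  n <- length(mol$elements)
  dist <- .point_atom_dist(grid)
  w <- matrix(1 / n, nrow(grid$points), n)
  pops <- as.numeric(crossprod(w, grid$w * rho))
  history <- numeric(0)
  converged <- FALSE
  profiles <- vector("list", n)
  it <- 0L
  ## the plain iteration contracts linearly (ratio often > 0.99 for bonded
  ## molecules); a periodic geometric extrapolation of the log-profiles
  ## accelerates it, and convergence is only ever declared from a genuine
  ## un-extrapolated iteration
  prev_log <- NULL; prev_delta <- NULL
  while (it < max_iter) {
    it <- it + 1L
    pro <- matrix(0, nrow(grid$points), n)
    for (a in seq_len(n)) {
      profiles[[a]] <- .spherical_average_profile(rho * w[, a], grid, a)
      pro[, a] <- .eval_profile(profiles[[a]], dist[, a])
    }
    cur_avg <- unlist(lapply(profiles, `[[`, "avg"))
    delta <- if (!is.null(prev_log)) cur_avg - prev_log else NULL
    did_extrapolate <- FALSE
    ## extrapolate only while far from the fixed point: close to it the
    ## secant estimate of the contraction ratio is noise-dominated and the
    ## jump can re-excite the iteration
    far <- length(history) == 0 || utils::tail(history, 1) > 50 * tol
    if (!is.null(prev_delta) && it %% 8L == 0L && far) {
      lam <- sum(delta * prev_delta) / sum(prev_delta^2)
      if (is.finite(lam) && lam > 0.5 && lam < 0.998) {
        cur_avg <- pmax(cur_avg + delta * lam / (1 - lam), .UNDERFLOW_FLOOR)
        lens <- vapply(profiles, function(p) length(p$avg), integer(1))
        new_avg <- split(cur_avg, rep(seq_len(n), lens))
        for (a in seq_len(n)) profiles[[a]]$avg <- new_avg[[a]]
        for (a in seq_len(n))
          pro[, a] <- .eval_profile(profiles[[a]], dist[, a])
        did_extrapolate <- TRUE
      }
    }
    prev_delta <- if (did_extrapolate) NULL else delta
    prev_log <- cur_avg
    w <- .stockholder_weights(pro, dist)
    new_pops <- as.numeric(crossprod(w, grid$w * rho))
    history <- c(history, max(abs(new_pops - pops)))
    delta_ok <- max(abs(new_pops - pops)) < tol && !did_extrapolate
    pops <- new_pops
    if (delta_ok) { converged <- TRUE; break }
  }
  if (!converged)
    warning("iterative stockholder did not converge in ", max_iter,
            " iterations")
  .new_partition_result("iterative-stockholder", w, rho, grid, it, converged,
                        history, extra = list(profiles = profiles))
}

#' Minimal-basis iterative stockholder (MBIS) partition
#'
#' Pro-atoms are sums of normalised Slater shells
#' `N_i zeta_i^3/(8 pi) exp(-zeta_i r)`; shell populations and exponents are
#' updated from the partitioned density until both are stationary:
#' `N_i <- integral rho s_i dV` and `zeta_i <- 3 N_i / integral rho s_i r dV`
#' with `s_i` the shell's stockholder share.
#'
#' @inheritParams iterative_hirshfeld
#' @param tol threshold on the largest shell-population change (e) and on
#'   the largest relative exponent change.
#' @return a `partition_result` with `shells`: per atom a 2 x k matrix of
#'   converged (N_i, zeta_i).
#' @export
mbis <- function(rho, grid, tol = 1e-6, max_iter = 500L) {
  mol <- grid$molecule
  n <- length(mol$elements)
  dist <- .point_atom_dist(grid)
  shells <- lapply(mol$elements, function(e) builtin_atom_table(e)$shells)
  wrho <- grid$w * rho
  history <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ## pro-density per shell and total
    shell_vals <- list()
    tot <- numeric(nrow(grid$points))
    for (a in seq_len(n)) {
      k <- ncol(shells[[a]])
      sv <- matrix(0, nrow(grid$points), k)
      for (i in seq_len(k)) {
        N <- shells[[a]][1, i]; z <- shells[[a]][2, i]
        sv[, i] <- N * z^3 / (8 * pi) * exp(-z * dist[, a])
      }
      shell_vals[[a]] <- sv
      tot <- tot + rowSums(sv)
    }
    tot <- pmax(tot, .UNDERFLOW_FLOOR)
    max_dn <- 0; max_dz <- 0
    for (a in seq_len(n)) {
      k <- ncol(shells[[a]])
      keep <- logical(k)
      for (i in seq_len(k)) {
        s <- shell_vals[[a]][, i] / tot
        N_new <- sum(wrho * s)
        denom <- sum(wrho * s * dist[, a])
        if (N_new < 1e-8 || denom <= 0) {
          warning("MBIS shell ", i, " of atom ", a,
                  " dropped (population below 1e-8 e)")
          keep[i] <- FALSE
          next
        }
        z_new <- 3 * N_new / denom
        max_dn <- max(max_dn, abs(N_new - shells[[a]][1, i]))
        max_dz <- max(max_dz, abs(z_new - shells[[a]][2, i]) /
                               shells[[a]][2, i])
        shells[[a]][1, i] <- N_new
        shells[[a]][2, i] <- z_new
        keep[i] <- TRUE
      }
      shells[[a]] <- shells[[a]][, keep, drop = FALSE]
    }
    history <- c(history, max(max_dn, max_dz))
    if (max_dn < tol && max_dz < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MBIS did not converge in ", max_iter, " iterations")
  ## final weights from the converged pro-atoms
  pro <- matrix(0, nrow(grid$points), n)
  for (a in seq_len(n)) pro[, a] <- atom_density_at(shells[[a]], dist[, a])
  w <- .stockholder_weights(pro, dist)
  .new_partition_result("mbis", w, rho, grid, it, converged, history,
                        extra = list(shells = shells))
}

#' Partition a density by a named scheme
#'
#' @param scheme one of `"becke"`, `"hirshfeld"`, `"iterative-hirshfeld"`,
#'   `"iterative-stockholder"`, `"mbis"`.
#' @inheritParams iterative_hirshfeld
#' @param ... passed to the iterative schemes (`tol`, `max_iter`).
#' @return a `partition_result`.
#' @export
partition_density <- function(scheme, rho, grid, ...) {
  scheme <- match.arg(scheme, c("becke", "hirshfeld", "iterative-hirshfeld",
                                "iterative-stockholder", "mbis"))
  switch(scheme,
         becke = becke_partition(rho, grid),
         hirshfeld = hirshfeld(rho, grid),
         `iterative-hirshfeld` = iterative_hirshfeld(rho, grid, ...),
         `iterative-stockholder` = iterative_stockholder(rho, grid, ...),
         mbis = mbis(rho, grid, ...))
}

#' Atomic charges and dipole moments of a partition
#'
#' `q_a = Z_a - N_a`; the dipole is the electron term about the atom's own
#' centre, `mu_a = -integral (r - R_a) rho_a(r) dV` (the nuclear term
#' vanishes about the atom's own position).
#'
#' @param result a `partition_result`.
#' @param grid the `molecular_grid` the partition was computed on.
#' @param order 0 (charges only) or 1 (charges and dipoles).
#' @return list with `charges` (e) and, for order 1, `dipoles`
#'   (n x 3, e angstrom).
#' @export
atomic_multipoles <- function(result, grid, order = 1) {
  if (!order %in% c(0, 1)) stop("only multipole orders 0 and 1 are supported")
  out <- list(charges = result$charges)
  if (order == 1) {
    mol <- grid$molecule
    n <- length(mol$elements)
    mu <- matrix(0, n, 3)
    for (a in seq_len(n)) {
      rho_a <- atomic_density(result, a)
      dx <- sweep(grid$points, 2, mol$cart[a, ])
      mu[a, ] <- -colSums(grid$w * rho_a * dx)
    }
    out$dipoles <- mu
  }
  out
}
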