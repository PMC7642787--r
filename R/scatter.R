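## From partitioned atomic densities to complex atomic form factors,
## Debye-Waller smearing, and structure factors; plus the point-charge/
## dipole cluster that represents the crystal field and the self-consistent
## multipole embedding loop.

#' Fourier transform of an atomic density on the grid
#'
#' `f_a(h) = integral rho_a(r) exp(2 pi i h . (r - R_a)) dV` by grid
#' quadrature, with `h` the Cartesian reciprocal vector of each reflection
#' (crystallographic `exp(+2 pi i h . r)` convention).
#'
#' @param rho_a atomic density values at the grid points.
#' @param grid a `molecular_grid`.
#' @param center length-3 Cartesian position of the atom (angstrom).
#' @param h_cart m x 3 matrix of reciprocal vectors (1/angstrom).
#' @param chunk reflections per trigonometry block (memory control).
#' @param drop_tol drop grid points whose absolute weighted density is below
#'   `drop_tol` times the total at h = 0 divided by the point count; 0 keeps
#'   every point.
#' @return complex vector of form factors (electrons).
#' @export
atomic_form_factor <- function(rho_a, grid, center, h_cart,
                               chunk = 128L, drop_tol = 1e-10) {
  h_cart <- rbind3(h_cart)
  wr <- grid$w * rho_a
  rel <- sweep(grid$points, 2, center)
  if (drop_tol > 0) {
    keep <- abs(wr) > drop_tol * sum(abs(wr)) / length(wr)
    wr <- wr[keep]; rel <- rel[keep, , drop = FALSE]
  }
  m <- nrow(h_cart)
  out <- complex(m)
  for (i0 in seq(1, m, by = chunk)) {
    i1 <- min(i0 + chunk - 1, m)
    ph <- 2 * pi * (rel %*% t(h_cart[i0:i1, , drop = FALSE]))
    out[i0:i1] <- as.complex(crossprod(cos(ph), wr)) +
      1i * as.complex(crossprod(sin(ph), wr))
  }
  out
}

#' Debye-Waller factor
#'
#' `T = exp(-2 pi^2 h^T U h)` with `U` the Cartesian ADP tensor and `h` the
#' Cartesian reciprocal vector (the convolution approximation for thermal
#' smearing).
#'
#' @param u_cart symmetric 3x3 Cartesian ADP tensor (angstrom^2).
#' @param h_cart m x 3 reciprocal vectors (1/angstrom).
#' @return numeric vector of smearing factors.
#' @export
debye_waller <- function(u_cart, h_cart) {
  stopifnot(max(abs(u_cart - t(u_cart))) < 1e-10)
  h_cart <- rbind3(h_cart)
  q <- rowSums((h_cart %*% u_cart) * h_cart)
  exp(-2 * pi^2 * q)
}

#' Tabulate aspherical atomic form factors for a structure
#'
#' Evaluates every site's partitioned density transform on the reflection
#' list, once per distinct symmetry rotation (aspherical form factors are
#' evaluated at the rotated scattering vector `R^T h`; the inverse rotation
#' reuses the conjugate since the densities are real).
#'
#' @param structure a [crystal_structure()]; sites must be in the same
#'   order as the grid's molecule atoms.
#' @param partition a `partition_result` for the asymmetric unit density.
#' @param grid the `molecular_grid` used for the partition.
#' @param hkl m x 3 integer matrix of Miller indices.
#' @param drop_tol passed to [atomic_form_factor()].
#' @return a `form_factor_table`: `hkl`, and `f` — a list over symmetry
#'   operations of complex (n_sites x m) matrices.
#' @export
form_factor_table <- function(structure, partition, grid, hkl,
                              drop_tol = 1e-10) {
  hkl <- rbind3(hkl)
  mol <- grid$molecule
  n <- length(structure$sites)
  if (n != length(mol$elements))
    stop("structure sites and grid molecule differ in atom count")
  ops <- structure$symops
  ## group operations by rotation matrix; +R and -R share one evaluation
  keys <- vapply(ops, function(op) paste(op$R, collapse = ","), character(1))
  neg_keys <- vapply(ops, function(op) paste(-op$R, collapse = ","), character(1))
  f_by_key <- list()
  f <- vector("list", length(ops))
  for (k in seq_along(ops)) {
    if (!is.null(f_by_key[[keys[k]]])) { f[[k]] <- f_by_key[[keys[k]]]; next }
    if (!is.null(f_by_key[[neg_keys[k]]])) {
      f[[k]] <- Conj(f_by_key[[neg_keys[k]]])
      f_by_key[[keys[k]]] <- f[[k]]
      next
    }
    hkl_rot <- hkl %*% ops[[k]]$R
    h_cart <- hkl_to_cart(structure$cell, hkl_rot)
    fk <- matrix(0i, n, nrow(hkl))
    for (a in seq_len(n))
      fk[a, ] <- atomic_form_factor(atomic_density(partition, a), grid,
                                    mol$cart[a, ], h_cart,
                                    drop_tol = drop_tol)
    f[[k]] <- fk
    f_by_key[[keys[k]]] <- fk
  }
  structure(list(hkl = hkl, f = f), class = "form_factor_table")
}

#' Structure factors from a form-factor table
#'
#' `F(h) = K sum_ops sum_a occ_a f_a(R^T h) T_a(R^T h) exp(2 pi i (h R . x_a
#' + h . t))`; Debye-Waller factors use each site's CIF-convention tensor
#' evaluated at the rotated index.
#'
#' @param structure a [crystal_structure()].
#' @param fftable a `form_factor_table` on the same reflection list.
#' @param scale overall scale factor K applied to F.
#' @return complex vector of F_calc.
#' @export
structure_factors <- function(structure, fftable, scale = 1) {
  hkl <- fftable$hkl
  cell <- structure$cell
  m <- nrow(hkl)
  n <- length(structure$sites)
  F <- complex(m)
  for (k in seq_along(structure$symops)) {
    op <- structure$symops[[k]]
    hkl_rot <- hkl %*% op$R
    g <- sweep(hkl_rot, 2, cell$recip, "*")  # for T in the CIF convention
    phase_t <- 2 * pi * as.numeric(hkl %*% op$t)
    fk <- fftable$f[[k]]
    if (is.null(fk)) stop("form factors missing for symmetry operation ", k)
    for (a in seq_len(n)) {
      s <- structure$sites[[a]]
      q <- rowSums((g %*% s$u_cif) * g)
      Tf <- exp(-2 * pi^2 * q)
      ph <- 2 * pi * as.numeric(hkl_rot %*% s$frac_pos) + phase_t
      F <- F + s$occupancy * fk[a, ] * Tf * exp(1i * ph)
    }
  }
  scale * F
}

## ---------------------------------------------------------------------
## Crystal-field cluster

#' Build the point-charge/dipole cluster around the central unit
#'
#' Enumerates whole-molecule symmetry/lattice images having at least one
#' atom within `cutoff` of any atom of the central (asymmetric-unit)
#' molecule and places the partition's charges and dipoles on their atoms;
#' each dipole is represented by a pair of charges `+-|mu|/s` separated by
#' `s = dipole_split` along the dipole direction.
#'
#' @param structure a [crystal_structure()] whose asymmetric unit is one
#'   bonded molecule.
#' @param charges per-site charges (e).
#' @param dipoles per-site dipole vectors (n x 3, e angstrom); NULL for
#'   charges only.
#' @param cutoff cluster radius (angstrom), default 8.
#' @param dipole_split charge-pair separation (angstrom), default 0.02.
#' @return a `multipole_cluster`: `charge_pos` (m x 3 Cartesian),
#'   `charge_q` (e), `n_molecules`, plus the call parameters.
#' @export
build_cluster <- function(structure, charges, dipoles = NULL, cutoff = 8,
                          dipole_split = 0.02) {
  if (cutoff <= 0) stop("cutoff must be positive")
  st <- site_table(structure)
  n <- nrow(st$frac)
  stopifnot(length(charges) == n)
  if (!is.null(dipoles)) { dipoles <- rbind3(dipoles); stopifnot(nrow(dipoles) == n) }
  ## asymmetric unit must be one covalently bonded molecule
  bonds <- detect_bonds(structure)
  if (n > 1) {
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (b in seq_len(nrow(bonds))) {
        i <- bonds[b, 1]; j <- bonds[b, 2]
        m <- min(comp[i], comp[j])
        if (comp[i] != m || comp[j] != m) { comp[i] <- comp[j] <- m; changed <- TRUE }
      }
      if (!changed) break
    }
    if (length(unique(comp)) > 1)
      stop("asymmetric unit is not a single bonded molecule (",
           length(unique(comp)), " fragments)")
  }
  cell <- structure$cell
  ## translation search range: cutoff plus molecular diameter, per axis
  diam <- if (n > 1) max(stats::dist(st$cart)) else 0
  reach <- cutoff + diam
  nmax <- ceiling(reach / c(cell$a, cell$b, cell$c)) + 1L
  qpos <- list(); qval <- list()
  n_mol <- 0L
  for (k in seq_along(structure$symops)) {
    op <- structure$symops[[k]]
    R_cart <- cell$ortho %*% op$R %*% cell$frac
    base_frac <- t(op$R %*% t(st$frac)) + matrix(op$t, n, 3, byrow = TRUE)
    for (t1 in -nmax[1]:nmax[1]) for (t2 in -nmax[2]:nmax[2])
      for (t3 in -nmax[3]:nmax[3]) {
        if (k == 1 && t1 == 0 && t2 == 0 && t3 == 0) next  # central unit
        fr <- sweep(base_frac, 2, c(t1, t2, t3), "+")
        ct <- frac_to_cart(cell, fr)
        ## within cutoff of any central atom?
        ok <- FALSE
        for (a in seq_len(n)) {
          dx <- sweep(st$cart, 2, ct[a, ])
          if (min(rowSums(dx * dx)) <= cutoff^2) { ok <- TRUE; break }
        }
        if (!ok) next
        n_mol <- n_mol + 1L
        qpos[[length(qpos) + 1]] <- ct
        qval[[length(qval) + 1]] <- charges
        if (!is.null(dipoles)) {
          mu_img <- dipoles %*% t(R_cart)
          mu_len <- sqrt(rowSums(mu_img^2))
          sel <- which(mu_len > 1e-14)
          for (a in sel) {
            u <- mu_img[a, ] / mu_len[a]
            q2 <- mu_len[a] / dipole_split
            qpos[[length(qpos) + 1]] <-
              rbind(ct[a, ] + u * dipole_split / 2,
                    ct[a, ] - u * dipole_split / 2)
            qval[[length(qval) + 1]] <- c(q2, -q2)
          }
        }
      }
  }
  structure(list(
    charge_pos = if (length(qpos)) do.call(rbind, qpos) else matrix(0, 0, 3),
    charge_q = if (length(qval)) unlist(qval) else numeric(0),
    n_molecules = n_mol, cutoff = cutoff, dipole_split = dipole_split),
    class = "multipole_cluster")
}

#' @export
print.multipole_cluster <- function(x, ...) {
  cat(sprintf("multipole cluster: %d image molecule(s), %d point charge(s), cutoff %.1f A\n",
              x$n_molecules, length(x$charge_q), x$cutoff))
  invisible(x)
}

#' Electric field of a cluster at given points
#'
#' Bare Coulomb sum over the cluster's point charges (dipoles are already
#' split into charge pairs, so the field felt is exactly the field the
#' refinement models): `E(r) = sum_q q (r - r_q)/|r - r_q|^3` in
#' e/angstrom^2.
#'
#' @param cluster a `multipole_cluster`.
#' @param points m x 3 Cartesian points (angstrom).
#' @return m x 3 matrix of field vectors.
#' @export
cluster_field <- function(cluster, points) {
  points <- rbind3(points)
  E <- matrix(0, nrow(points), 3)
  if (length(cluster$charge_q) == 0) return(E)
  for (i in seq_len(nrow(points))) {
    dx <- sweep(matrix(points[i, ], nrow(cluster$charge_pos), 3,
                       byrow = TRUE), 1, 0) - cluster$charge_pos
    r3 <- (rowSums(dx * dx))^(3 / 2)
    E[i, ] <- colSums(cluster$charge_q * dx / r3)
  }
  E
}

#' Self-consistent multipole embedding
#'
#' Alternates (i) Hirshfeld charges and dipoles of the current density —
#' the field source is always the Hirshfeld partition, whichever partition
#' the form factors use — (ii) cluster rebuild, (iii) Coulomb field at the
#' atomic centres, (iv) linear repolarization `d_a = alpha_a E(R_a)`, until
#' the largest change of any charge or dipole component is below `tol`
#' atomic units (1 a.u. charge = 1 e; 1 a.u. dipole = 0.52917721 e angstrom).
#'
#' @param structure a [crystal_structure()].
#' @param model starting `density_model` for the asymmetric unit.
#' @param grid a `molecular_grid` for the asymmetric unit (reused across
#'   iterations).
#' @param cutoff cluster radius (angstrom).
#' @param dipole_split dipole charge-pair separation (angstrom).
#' @param tol convergence threshold in atomic units (default 0.003).
#' @param max_iter iteration cap.
#' @return list with the polarized `model`, final `cluster`, final
#'   `charges`/`dipoles`, `iterations`, `converged`, `history` (largest
#'   multipole component change in a.u. per iteration).
#' @export
self_consistent_embedding <- function(structure, model, grid, cutoff = 8,
                                      dipole_split = 0.02, tol = 0.003,
                                      max_iter = 50L) {
  st <- site_table(structure)
  q_old <- NULL; mu_old <- NULL
  history <- numeric(0)
  converged <- FALSE
  cluster <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    rho <- polarized_density(model, grid$points)
    part <- hirshfeld(rho, grid)
    mp <- atomic_multipoles(part, grid, order = 1)
    if (!is.null(q_old)) {
      delta <- max(max(abs(mp$charges - q_old)),
                   max(abs(mp$dipoles - mu_old)) / AU_DIPOLE_EA)
      history <- c(history, delta)
      if (delta < tol) { converged <- TRUE }
    }
    q_old <- mp$charges; mu_old <- mp$dipoles
    cluster <- build_cluster(structure, mp$charges, mp$dipoles,
                             cutoff = cutoff, dipole_split = dipole_split)
    if (converged) break
    E <- cluster_field(cluster, st$cart)
    model <- polarize_model(model, E)
    ## a rigid model (all polarizabilities zero) is converged after one pass
    if (all(model$polarizability == 0) && it == 1) {
      converged <- TRUE
      history <- c(history, 0)
      break
    }
  }
  if (!converged)
    warning("multipole embedding did not converge in ", max_iter,
            " iterations")
  list(model = model, cluster = cluster, charges = q_old, dipoles = mu_old,
       iterations = it, converged = converged, history = history)
}
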