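## Statistics comparing an X-ray-refined structure against a neutron
## benchmark: bond-length and ADP discrepancy aggregates (weighted RMS
## differences), the S12 similarity index of ADP-defined Gaussian
## probability densities, thermal-ellipsoid volume ratios, the
## population standard deviation attached to every mean, and the isotropic
## least-squares rescaling of neutron ADPs.

#' Population standard deviation
#'
#' Uses the population convention (divide by n, not n - 1); this is the
#' spread quoted in brackets after every reported average.
#'
#' @param x numeric vector.
#' @return `sqrt(mean((x - mean(x))^2))`.
#' @export
population_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Bond-length discrepancy statistics
#'
#' `dR = R_X - R_N` per bond (reported in milli-angstrom), with
#' `wRMSD = sqrt(mean(dR^2 / sigma^2(dR)))` where
#' `sigma^2(dR) = sigma_X^2 + sigma_N^2` (independent measurements), the
#' plain means `<dR>`, `<|dR|>` and `<R_X/R_N>`, and the population SD of
#' each mean.
#'
#' @param struct_x,struct_n X-ray and neutron [crystal_structure()]s with
#'   matching site labels.
#' @param bonds two-column matrix of site labels (character) or of indices
#'   into `struct_x`.
#' @param sigma_x,sigma_n per-bond length standard uncertainties
#'   (angstrom); scalars recycle.  Bonds with both sigmas zero are excluded
#'   from the wRMSD with a warning.
#' @return list with per-bond table `bonds` and aggregates `mean_dr`,
#'   `mean_abs_dr`, `wrmsd`, `mean_ratio` (each with `*_sd` population
#'   spreads); lengths in milli-angstrom.
#' @export
bond_stats <- function(struct_x, struct_n, bonds, sigma_x = 0, sigma_n = 0) {
  lab_x <- vapply(struct_x$sites, `[[`, character(1), "label")
  lab_n <- vapply(struct_n$sites, `[[`, character(1), "label")
  if (is.character(bonds)) {
    bl <- matrix(match(bonds, lab_x), ncol = 2)
    if (anyNA(bl)) stop("bond label(s) not in X-ray structure: ",
                        paste(bonds[is.na(match(bonds, lab_x))], collapse = ", "))
    labels <- matrix(bonds, ncol = 2)
  } else {
    bl <- rbind3(bonds)[, 1:2, drop = FALSE]
    labels <- matrix(lab_x[bl], ncol = 2)
  }
  bn <- matrix(match(labels, lab_n), ncol = 2)
  if (anyNA(bn)) stop("bond label(s) not in neutron structure: ",
                      paste(labels[is.na(bn)], collapse = ", "))
  nb <- nrow(bl)
  sigma_x <- rep_len(sigma_x, nb); sigma_n <- rep_len(sigma_n, nb)
  rx <- bond_lengths(struct_x, bl)
  rn <- bond_lengths(struct_n, bn)
  dr <- (rx - rn) * 1e3                      # milli-angstrom
  sig <- sqrt(sigma_x^2 + sigma_n^2) * 1e3
  wr_terms <- dr^2 / sig^2
  zero <- sig == 0
  if (any(zero)) {
    warning(sum(zero), " bond(s) with sigma_X = sigma_N = 0 excluded from wRMSD")
    wr_terms <- wr_terms[!zero]
  }
  tab <- data.frame(label_i = labels[, 1], label_j = labels[, 2],
                    r_x = rx, r_n = rn, dr_mA = dr, sigma_dr_mA = sig)
  list(bonds = tab,
       mean_dr = mean(dr), mean_dr_sd = population_sd(dr),
       mean_abs_dr = mean(abs(dr)), mean_abs_dr_sd = population_sd(abs(dr)),
       wrmsd = if (length(wr_terms)) sqrt(mean(wr_terms)) else NA_real_,
       mean_ratio = mean(rx / rn), mean_ratio_sd = population_sd(rx / rn))
}

#' ADP discrepancy statistics
#'
#' Compares the six unique Cartesian tensor components per atom:
#' `<|dU_ij|>` as a flat mean over all components of all atoms, the
#' weighted RMS difference with `sigma^2(dU) = sigma_X^2 + sigma_N^2`, and
#' per-atom S12 and ellipsoid-volume ratios.
#'
#' @param struct_x,struct_n structures with matching labels.
#' @param atoms character vector of site labels to compare (default: all
#'   shared labels).
#' @param sigma_x,sigma_n per-atom 3x3 matrices (lists, in `atoms` order)
#'   of component uncertainties, or a scalar.
#' @return list with per-atom table `atoms` (mean |dU|, S12, V ratio per
#'   atom) and aggregates `mean_abs_du`, `mean_abs_du_sd`, `wrmsd`,
#'   `mean_s12`, `mean_s12_sd`, `mean_vratio`, `mean_vratio_sd`.
#' @export
adp_stats <- function(struct_x, struct_n, atoms = NULL,
                      sigma_x = 0, sigma_n = 0) {
  lab_x <- vapply(struct_x$sites, `[[`, character(1), "label")
  lab_n <- vapply(struct_n$sites, `[[`, character(1), "label")
  if (is.null(atoms)) atoms <- intersect(lab_x, lab_n)
  ui <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  get_sig <- function(s, k) {
    if (is.list(s)) s[[k]] else matrix(s, 3, 3)
  }
  du_all <- numeric(0); wr_all <- numeric(0)
  per_atom <- NULL
  for (k in seq_along(atoms)) {
    ix <- match(atoms[k], lab_x); im <- match(atoms[k], lab_n)
    if (is.na(ix) || is.na(im)) {
      warning("atom ", atoms[k], " missing; skipped")
      next
    }
    ux <- u_cif_to_cartesian(struct_x$sites[[ix]]$u_cif, struct_x$cell)
    un <- u_cif_to_cartesian(struct_n$sites[[im]]$u_cif, struct_n$cell)
    sx <- get_sig(sigma_x, k); sn <- get_sig(sigma_n, k)
    comp_d <- ux[cbind(ui[, 1], ui[, 2])] - un[cbind(ui[, 1], ui[, 2])]
    comp_s2 <- sx[cbind(ui[, 1], ui[, 2])]^2 + sn[cbind(ui[, 1], ui[, 2])]^2
    du_all <- c(du_all, abs(comp_d))
    ok <- comp_s2 > 0
    wr_all <- c(wr_all, comp_d[ok]^2 / comp_s2[ok])
    per_atom <- rbind(per_atom, data.frame(
      label = atoms[k], mean_abs_du = mean(abs(comp_d)),
      s12 = s12(ux, un), vratio = volume_ratio(ux, un)))
  }
  list(atoms = per_atom,
       mean_abs_du = mean(du_all), mean_abs_du_sd = population_sd(du_all),
       wrmsd = if (length(wr_all)) sqrt(mean(wr_all)) else NA_real_,
       mean_s12 = mean(per_atom$s12), mean_s12_sd = population_sd(per_atom$s12),
       mean_vratio = mean(per_atom$vratio),
       mean_vratio_sd = population_sd(per_atom$vratio))
}

#' S12 similarity index of two ADP tensors
#'
#' `S12 = 100 (1 - R12)` with `R12` the overlap of the two trivariate
#' Gaussian probability densities defined by the tensors, evaluated in
#' closed form:
#' `R12 = 2^{3/2} [det U1 det U2]^{-1/4} [det(U1^{-1} + U2^{-1})]^{-1/2}`.
#' 0 means identical ellipsoids.
#'
#' @param u1,u2 symmetric positive definite 3x3 Cartesian ADP tensors.
#' @return S12 (dimensionless, >= 0).
#' @export
s12 <- function(u1, u2) {
  for (u in list(u1, u2)) {
    ev <- eigen(u, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("S12 undefined: ADP tensor not positive definite")
  }
  r12 <- 2^1.5 * (det(u1) * det(u2))^(-0.25) *
    det(solve(u1) + solve(u2))^(-0.5)
  100 * (1 - r12)
}

#' Overlap R12 of two ADP-defined Gaussians by direct numerical integration
#'
#' Independent check of the closed form: integrates
#' `sqrt(p1 p2) / sqrt(int p1 int p2)` on a Cartesian raster spanning
#' +-`extent` standard deviations of the average tensor.
#'
#' @param u1,u2 SPD 3x3 tensors (angstrom^2).
#' @param n raster points per axis.
#' @param extent half-width in standard deviations.
#' @return numerical R12.
#' @export
r12_numeric <- function(u1, u2, n = 81L, extent = 7) {
  ## whitened frame of the average tensor keeps the raster efficient
  um <- (u1 + u2) / 2
  e <- eigen(um, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(e$values))
  s <- seq(-extent, extent, length.out = n)
  h <- s[2] - s[1]
  gpts <- as.matrix(expand.grid(s, s, s))
  x <- gpts %*% t(L)
  q1 <- rowSums((x %*% solve(u1)) * x)
  q2 <- rowSums((x %*% solve(u2)) * x)
  jac <- abs(det(L))
  p1 <- exp(-0.5 * q1) / sqrt((2 * pi)^3 * det(u1))
  p2 <- exp(-0.5 * q2) / sqrt((2 * pi)^3 * det(u2))
  vol <- h^3 * jac
  sum(sqrt(p1 * p2)) * vol / sqrt(sum(p1) * vol * sum(p2) * vol)
}

#' Ratio of thermal-ellipsoid volumes
#'
#' The ellipsoid volume is proportional to the product of the semi-axes,
#' i.e. to the square root of the tensor determinant, so
#' `V_X / V_N = sqrt(det U_X / det U_N)`.
#'
#' @param u_x,u_n SPD 3x3 Cartesian ADP tensors.
#' @return the volume ratio (> 0).
#' @export
volume_ratio <- function(u_x, u_n) {
  for (u in list(u_x, u_n)) {
    ev <- eigen(u, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("volume ratio undefined: tensor not positive definite")
  }
  sqrt(det(u_x) / det(u_n))
}

#' Isotropic least-squares rescaling of neutron ADPs
#'
#' `k = argmin sum (U_X,ij - k U_N,ij)^2 = sum U_X U_N / sum U_N^2` over
#' the six unique components of the selected atoms (conventionally the
#' non-hydrogen atoms); used to remove a global temperature-like mismatch
#' between the two experiments.
#'
#' @param u_x_list,u_n_list lists of 3x3 CIF or Cartesian tensors (same
#'   convention for both), in matching atom order.
#' @param selection indices of atoms entering the fit (default: all).
#' @return list with `k` and `rescaled` (k times every tensor of
#'   `u_n_list`).
#' @export
scale_neutron_adps <- function(u_x_list, u_n_list, selection = NULL) {
  stopifnot(length(u_x_list) == length(u_n_list))
  if (is.null(selection)) selection <- seq_along(u_x_list)
  if (length(selection) == 0) stop("empty atom selection")
  ui <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  num <- 0; den <- 0
  for (a in selection) {
    cx <- u_x_list[[a]][cbind(ui[, 1], ui[, 2])]
    cn <- u_n_list[[a]][cbind(ui[, 1], ui[, 2])]
    num <- num + sum(cx * cn)
    den <- den + sum(cn^2)
  }
  if (den == 0) stop("neutron ADPs are all zero; scale undefined")
  k <- num / den
  list(k = k, rescaled = lapply(u_n_list, function(u) k * u))
}
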