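## Weighted least-squares refinement against F_o^2 with weights 1/sigma^2
## (no auxiliary weighting-scheme parameters): Gauss-Newton with analytic
## derivatives of |F_c|^2 with respect to fractional coordinates and
## CIF-convention U_ij, the overall scale treated as a linear parameter at
## each step, and step halving so the weighted residual never increases
## within accepted steps.

## parameter bookkeeping: data frame of (site, kind, i, j) rows; kind in
## {scale, x, u}
.param_layout <- function(structure, refine_xyz, refine_u) {
  n <- length(structure$sites)
  rows <- list(data.frame(site = 0L, kind = "scale", i = 0L, j = 0L))
  uidx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  for (a in seq_len(n)) {
    if (refine_xyz[a])
      rows[[length(rows) + 1]] <- data.frame(site = a, kind = "x",
                                             i = 1:3, j = 0L)
    if (refine_u[a])
      rows[[length(rows) + 1]] <- data.frame(site = a, kind = "u",
                                             i = uidx[, 1], j = uidx[, 2])
  }
  do.call(rbind, rows)
}

.param_names <- function(layout, structure) {
  labs <- vapply(structure$sites, `[[`, character(1), "label")
  nm <- character(nrow(layout))
  for (r in seq_len(nrow(layout))) {
    if (layout$kind[r] == "scale") nm[r] <- "K"
    else if (layout$kind[r] == "x")
      nm[r] <- paste0(labs[layout$site[r]], ".", c("x", "y", "z")[layout$i[r]])
    else nm[r] <- sprintf("%s.U%d%d", labs[layout$site[r]],
                          layout$i[r], layout$j[r])
  }
  nm
}

## F_calc (without scale) and complex derivative blocks for every site
.fc_and_derivs <- function(structure, fftable, want_derivs = TRUE) {
  hkl <- fftable$hkl
  cell <- structure$cell
  m <- nrow(hkl)
  n <- length(structure$sites)
  F <- complex(m)
  dX <- if (want_derivs) replicate(n, matrix(0i, m, 3), simplify = FALSE)
  dU <- if (want_derivs) replicate(n, matrix(0i, m, 6), simplify = FALSE)
  uidx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  for (k in seq_along(structure$symops)) {
    op <- structure$symops[[k]]
    hkl_rot <- hkl %*% op$R
    g <- sweep(hkl_rot, 2, cell$recip, "*")
    phase_t <- 2 * pi * as.numeric(hkl %*% op$t)
    fk <- fftable$f[[k]]
    for (a in seq_len(n)) {
      s <- structure$sites[[a]]
      q <- rowSums((g %*% s$u_cif) * g)
      Tf <- exp(-2 * pi^2 * q)
      ph <- 2 * pi * as.numeric(hkl_rot %*% s$frac_pos) + phase_t
      ca <- s$occupancy * fk[a, ] * Tf * exp(1i * ph)
      F <- F + ca
      if (want_derivs) {
        dX[[a]] <- dX[[a]] + (2i * pi) * hkl_rot * ca
        for (u in 1:6) {
          fac <- if (u <= 3) 1 else 2  # off-diagonals appear twice
          dU[[a]][, u] <- dU[[a]][, u] -
            2 * pi^2 * fac * g[, uidx[u, 1]] * g[, uidx[u, 2]] * ca
        }
      }
    }
  }
  list(F = F, dX = dX, dU = dU)
}

#' Weighted least-squares refinement against F_o^2
#'
#' Minimises `sum w (F_o^2 - K |F_c|^2)^2` with `w = 1/sigma^2(F_o^2)` by
#' Gauss-Newton with analytic derivatives; the overall scale K is reset to
#' its closed-form optimum before each step and refined jointly.  Standard
#' uncertainties come from the inverse normal matrix, by default rescaled
#' by the goodness of fit.
#'
#' @param structure starting [crystal_structure()].
#' @param reflections a [reflection_set()]; only usable reflections
#'   (sigma > 0) enter the target.
#' @param fftable a `form_factor_table` on the same index list (held fixed
#'   during the refinement).
#' @param refine_xyz,refine_u logical, per site or scalar: which positions
#'   and ADP tensors to refine.
#' @param max_cycles Gauss-Newton iteration cap.
#' @param gof_rescale rescale parameter sigmas by the goodness of fit.
#' @return a `refinement_result`: refined `structure`, `scale`, `r1`,
#'   `wr2`, `gof`, `sigmas` (named), `covariance`, `cycles`, `converged`,
#'   `f_calc` (unscaled), `layout`, `nonpositive_u` flags.
#' @export
lsq_refine <- function(structure, reflections, fftable,
                       refine_xyz = TRUE, refine_u = TRUE,
                       max_cycles = 40L, gof_rescale = TRUE) {
  n <- length(structure$sites)
  refine_xyz <- rep_len(refine_xyz, n)
  refine_u <- rep_len(refine_u, n)
  use <- reflections$usable
  if (!any(use)) stop("no usable reflections (all sigma <= 0)")
  if (!all(dim(fftable$hkl) == dim(reflections$hkl)) ||
      !all(fftable$hkl == reflections$hkl))
    stop("form-factor table and reflection set have different index lists")
  yobs <- reflections$f_obs_sq[use]
  sw <- 1 / reflections$sigma[use]
  layout <- .param_layout(structure, refine_xyz, refine_u)
  np <- nrow(layout)
  uidx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))

  cur <- structure
  fd <- .fc_and_derivs(cur, fftable)
  K <- {
    y2 <- abs(fd$F[use])^2
    sum(sw^2 * yobs * y2) / sum(sw^2 * y2^2)
  }
  wssq <- sum((sw * (yobs - K * abs(fd$F[use])^2))^2)
  cycles <- 0L
  converged <- FALSE
  A <- NULL
  while (cycles < max_cycles) {
    cycles <- cycles + 1L
    Fu <- fd$F[use]
    y2 <- abs(Fu)^2
    ## jacobian of the model K|F|^2 in sqrt(w) units
    A <- matrix(0, sum(use), np)
    for (r in seq_len(np)) {
      if (layout$kind[r] == "scale") { A[, r] <- sw * y2; next }
      a <- layout$site[r]
      dF <- if (layout$kind[r] == "x") fd$dX[[a]][use, layout$i[r]]
            else fd$dU[[a]][use, match(paste(layout$i[r], layout$j[r]),
                                       paste(uidx[, 1], uidx[, 2]))]
      A[, r] <- sw * K * 2 * Re(Conj(Fu) * dF)
    }
    yres <- sw * (yobs - K * y2)
    AtA <- crossprod(A)
    rhs <- crossprod(A, yres)
    delta <- tryCatch(solve(AtA, rhs), error = function(e) {
      ev <- eigen(AtA, symmetric = TRUE)
      null <- which(ev$values < max(ev$values) * 1e-12)
      bad <- unique(unlist(lapply(null, function(k)
        .param_names(layout, cur)[abs(ev$vectors[, k]) > 0.3])))
      stop("singular normal matrix; null-space parameters: ",
           paste(bad, collapse = ", "))
    })
    ## step halving: never accept an increase of the weighted residual
    step <- 1
    repeat {
      trial <- cur
      d <- delta * step
      for (r in seq_len(np)) {
        if (layout$kind[r] == "scale") { K_trial <- K + d[r]; next }
        a <- layout$site[r]
        if (layout$kind[r] == "x") {
          trial$sites[[a]]$frac_pos[layout$i[r]] <-
            trial$sites[[a]]$frac_pos[layout$i[r]] + d[r]
        } else {
          i <- layout$i[r]; j <- layout$j[r]
          trial$sites[[a]]$u_cif[i, j] <- trial$sites[[a]]$u_cif[i, j] + d[r]
          if (i != j) trial$sites[[a]]$u_cif[j, i] <- trial$sites[[a]]$u_cif[i, j]
        }
      }
      fd_trial <- .fc_and_derivs(trial, fftable)
      y2t <- abs(fd_trial$F[use])^2
      K_opt <- sum(sw^2 * yobs * y2t) / sum(sw^2 * y2t^2)
      wssq_trial <- sum((sw * (yobs - K_opt * y2t))^2)
      if (wssq_trial <= wssq * (1 + 1e-14) || step < 1 / 1024) break
      step <- step / 2
    }
    shift <- max(abs(delta * step))
    improved <- wssq - wssq_trial
    cur <- trial; fd <- fd_trial; K <- K_opt
    wssq_old <- wssq; wssq <- wssq_trial
    if (shift < 1e-9 || (improved >= 0 && improved < 1e-14 * max(wssq_old, 1e-300))) {
      converged <- TRUE
      break
    }
  }
  ## statistics and uncertainties at the converged point
  Fu <- fd$F[use]
  y2 <- abs(Fu)^2
  yres <- sw * (yobs - K * y2)
  wr2 <- sqrt(sum(yres^2) / sum((sw * yobs)^2))
  fo <- sqrt(pmax(yobs, 0))
  fc <- sqrt(K) * abs(Fu)
  r1 <- sum(abs(fo - fc)) / sum(fo)
  dof <- max(1L, sum(use) - np)
  gof <- sqrt(sum(yres^2) / dof)
  AtA <- crossprod(A)
  cov <- tryCatch(solve(AtA), error = function(e) {
    warning("normal matrix singular at convergence; covariance unavailable")
    matrix(NA_real_, np, np)
  })
  if (gof_rescale) cov <- cov * gof^2
  sig <- sqrt(pmax(diag(cov), 0))
  names(sig) <- .param_names(layout, cur)
  nonpos <- vapply(cur$sites, function(s) {
    ev <- eigen(u_cif_to_cartesian(s$u_cif, cur$cell), symmetric = TRUE,
                only.values = TRUE)$values
    any(ev <= 0)
  }, logical(1))
  if (any(nonpos))
    warning("refined ADP tensor not positive definite for site(s): ",
            paste(which(nonpos), collapse = ", "))
  structure(list(structure = cur, scale = K, r1 = r1, wr2 = wr2, gof = gof,
                 sigmas = sig, covariance = cov, cycles = cycles,
                 converged = converged, f_calc = fd$F,
                 layout = layout, nonpositive_u = nonpos,
                 wssq = wssq, n_used = sum(use)),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement: %d cycle(s), %s  K=%.6g  R1=%.4f  wR2=%.4f  GooF=%.3f\n",
              x$cycles, if (x$converged) "converged" else "NOT converged",
              x$scale, x$r1, x$wr2, x$gof))
  invisible(x)
}

#' Bond lengths with propagated standard uncertainties
#'
#' Propagates the refinement's coordinate covariance through the bond-length
#' gradient (correlations between the two sites included).
#'
#' @param result a `refinement_result`.
#' @param bonds two-column matrix of site index pairs.
#' @return data frame with `i`, `j`, `length` (angstrom) and `sigma`
#'   (angstrom; 0 when a coordinate was not refined).
#' @export
bond_length_sigmas <- function(result, bonds) {
  structure_ <- result$structure
  st <- site_table(structure_)
  layout <- result$layout
  out <- data.frame(i = bonds[, 1], j = bonds[, 2],
                    length = bond_lengths(structure_, bonds), sigma = 0)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    dvec <- st$cart[i, ] - st$cart[j, ]
    len <- sqrt(sum(dvec * dvec))
    ## d(len)/d(frac_i) = (A^T dvec)/len ; opposite sign for j
    gfrac <- as.numeric(t(structure_$cell$ortho) %*% dvec) / len
    rows_i <- which(layout$site == i & layout$kind == "x")
    rows_j <- which(layout$site == j & layout$kind == "x")
    g <- numeric(nrow(layout))
    if (length(rows_i)) g[rows_i] <- gfrac[layout$i[rows_i]]
    if (length(rows_j)) g[rows_j] <- -gfrac[layout$i[rows_j]]
    v <- as.numeric(t(g) %*% result$covariance %*% g)
    out$sigma[b] <- sqrt(max(v, 0))
  }
  out
}

#' Standard uncertainties of the ADP components of one site
#'
#' @param result a `refinement_result`.
#' @param site site index.
#' @return symmetric 3x3 matrix of sigma(U_ij) in CIF convention (zeros
#'   when the site's ADPs were not refined).
#' @export
adp_sigmas <- function(result, site) {
  layout <- result$layout
  s <- matrix(0, 3, 3)
  rows <- which(layout$site == site & layout$kind == "u")
  for (r in rows) {
    i <- layout$i[r]; j <- layout$j[r]
    s[i, j] <- s[j, i] <- result$sigmas[r]
  }
  s
}
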