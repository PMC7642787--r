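## The generalized-atom-refinement outer loop: rebuild the density at the
## current geometry (with optional crystal-field embedding), partition it,
## recompute aspherical form factors, refine, and repeat until both the
## largest atomic displacement and the largest covalent-bond-length change
## drop below threshold; oscillations are damped by averaging the
## structural parameters and form factors of the last two cycles.

#' Settings for a GAR run
#'
#' @param scheme partition scheme (see [partition_density()]).
#' @param grid_spec a [grid_spec()] for density grids.
#' @param embedding logical: surround the molecule with self-consistent
#'   point charges and dipoles.
#' @param cutoff embedding cluster radius (angstrom), default 8.
#' @param dipole_split dipole charge-pair separation (angstrom), default 0.02.
#' @param embed_tol embedding convergence threshold (a.u.), default 0.003.
#' @param geom_tol outer-loop geometry threshold (angstrom) on both the
#'   largest atomic displacement and the largest covalent-bond change,
#'   default 0.001.
#' @param damping `"auto"` (two-cycle averaging switched on when an
#'   oscillation is detected), `"on"`, or `"off"`.
#' @param max_outer outer iteration cap.
#' @param partition_tol,partition_max_iter forwarded to iterative schemes.
#' @param model_fn function(structure) returning the `density_model` for the
#'   current geometry; defaults to the unpolarized promolecule.  Lets a
#'   fixture supply static bond dipoles or exaggerated geometry-density
#'   coupling.
#' @return a `gar_settings` list.
#' @export
gar_settings <- function(scheme = "hirshfeld",
                         grid_spec = production_grid_spec(),
                         embedding = FALSE, cutoff = 8, dipole_split = 0.02,
                         embed_tol = 0.003, geom_tol = 0.001,
                         damping = c("auto", "off", "on"),
                         max_outer = 15L,
                         partition_tol = 1e-6, partition_max_iter = 500L,
                         model_fn = NULL) {
  stopifnot(geom_tol > 0, embed_tol > 0, cutoff > 0, max_outer >= 1)
  if (is.null(model_fn)) model_fn <- molecular_density_model
  structure(list(scheme = scheme, grid_spec = grid_spec,
                 embedding = embedding, cutoff = cutoff,
                 dipole_split = dipole_split, embed_tol = embed_tol,
                 geom_tol = geom_tol, damping = match.arg(damping),
                 max_outer = as.integer(max_outer),
                 partition_tol = partition_tol,
                 partition_max_iter = as.integer(partition_max_iter),
                 model_fn = model_fn),
            class = "gar_settings")
}

## flat numeric vector of the refinable structural parameters
.structure_params <- function(structure) {
  unlist(lapply(structure$sites, function(s)
    c(s$frac_pos, s$u_cif[1, 1], s$u_cif[2, 2], s$u_cif[3, 3],
      s$u_cif[2, 3], s$u_cif[1, 3], s$u_cif[1, 2])))
}

.set_structure_params <- function(structure, p) {
  k <- 0
  for (a in seq_along(structure$sites)) {
    structure$sites[[a]]$frac_pos <- p[k + 1:3]
    u <- matrix(0, 3, 3)
    u[1, 1] <- p[k + 4]; u[2, 2] <- p[k + 5]; u[3, 3] <- p[k + 6]
    u[2, 3] <- u[3, 2] <- p[k + 7]
    u[1, 3] <- u[3, 1] <- p[k + 8]
    u[1, 2] <- u[2, 1] <- p[k + 9]
    structure$sites[[a]]$u_cif <- u
    k <- k + 9
  }
  structure
}

.average_fftable <- function(f1, f2) {
  f1$f <- lapply(seq_along(f1$f), function(k) (f1$f[[k]] + f2$f[[k]]) / 2)
  f1
}

#' Run the GAR outer loop
#'
#' @param structure starting [crystal_structure()].
#' @param reflections a [reflection_set()].
#' @param settings a [gar_settings()].
#' @param verbose print one line per outer cycle.
#' @return a `gar_result`: final `refinement` (a `refinement_result`),
#'   `structure`, `trace` (data frame: cycle, max displacement, max bond
#'   change, R1, wR2, scale, damped flag), `converged`, `cycles`,
#'   `partition` (last `partition_result`), `embedding` (last embedding
#'   record or NULL).
#' @export
gar_loop <- function(structure, reflections, settings = gar_settings(),
                     verbose = FALSE) {
  cur <- structure
  bonds <- detect_bonds(structure)
  trace <- NULL
  converged <- FALSE
  averaging <- settings$damping == "on"
  osc_count <- 0L
  prev_delta <- NULL
  prev_fft <- NULL
  prev_params <- NULL
  refinement <- NULL
  part <- NULL
  emb <- NULL
  for (cycle in seq_len(settings$max_outer)) {
    grid <- build_molecular_grid(cur, settings$grid_spec)
    model <- settings$model_fn(cur)
    if (settings$embedding) {
      emb <- self_consistent_embedding(cur, model, grid,
                                       cutoff = settings$cutoff,
                                       dipole_split = settings$dipole_split,
                                       tol = settings$embed_tol)
      model <- emb$model
    }
    rho <- density_on_grid(model, grid)
    part <- partition_density(settings$scheme, rho, grid,
                              tol = settings$partition_tol,
                              max_iter = settings$partition_max_iter)
    fft <- form_factor_table(cur, part, grid, reflections$hkl)
    fft_used <- if (averaging && !is.null(prev_fft))
      .average_fftable(fft, prev_fft) else fft
    refinement <- lsq_refine(cur, reflections, fft_used)
    new_params <- .structure_params(refinement$structure)
    if (averaging && !is.null(prev_params))
      new_params <- (new_params + prev_params) / 2
    new <- .set_structure_params(cur, new_params)
    ## geometry change between the refined structure and the one the
    ## density was computed for
    old_cart <- site_table(cur)$cart
    new_cart <- site_table(new)$cart
    dxyz <- max(sqrt(rowSums((new_cart - old_cart)^2)))
    dbond <- if (nrow(bonds)) max(abs(bond_lengths(new, bonds) -
                                      bond_lengths(cur, bonds))) else 0
    delta <- new_params - .structure_params(cur)
    damped_now <- averaging
    step_cos <- if (is.null(prev_delta)) NA_real_ else
      sum(delta * prev_delta) /
        max(sqrt(sum(delta^2) * sum(prev_delta^2)), 1e-300)
    trace <- rbind(trace, data.frame(
      cycle = cycle, max_dxyz = dxyz, max_dbond = dbond,
      r1 = refinement$r1, wr2 = refinement$wr2,
      scale = refinement$scale, damped = damped_now,
      step_cos = step_cos))
    if (verbose)
      cat(sprintf("cycle %2d  max|dx| %.6f A  max|db| %.6f A  R1 %.4f  wR2 %.4f%s\n",
                  cycle, dxyz, dbond, refinement$r1, refinement$wr2,
                  if (damped_now) "  [averaged]" else ""))
    ## oscillation detection: geometry steps reversing direction in three
    ## consecutive cycles
    if (!averaging && settings$damping == "auto" && !is.null(prev_delta)) {
      if (sum(delta * prev_delta) < 0) osc_count <- osc_count + 1L
      else osc_count <- 0L
      if (osc_count >= 3L) averaging <- TRUE
    }
    prev_delta <- delta
    prev_fft <- fft
    prev_params <- new_params
    cur <- new
    if (dxyz < settings$geom_tol && dbond < settings$geom_tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(refinement = refinement, structure = cur, trace = trace,
                 converged = converged, cycles = nrow(trace),
                 partition = part, embedding = emb,
                 settings = settings),
            class = "gar_result")
}

#' @export
print.gar_result <- function(x, ...) {
  cat(sprintf("GAR (%s): %d outer cycle(s), %s; final R1=%.4f wR2=%.4f\n",
              x$settings$scheme, x$cycles,
              if (x$converged) "converged" else "NOT converged",
              x$refinement$r1, x$refinement$wr2))
  invisible(x)
}
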