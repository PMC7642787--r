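## Becke-type multicenter integration: power-transform radial grids,
## angular quadrature rules on the sphere, smoothed Voronoi (Becke) cell
## weights, and their fusion into a molecular grid.

#' Power-transform radial quadrature grid
#'
#' Nodes `r_j = a x_j^p` with `x_j` midpoint-uniform on (0, 1]; the weights
#' carry the transform Jacobian `p a x^(p-1)` and the spherical `r^2`
#' measure, so `sum(w * f(r)) * (angular weight sum)` approximates
#' `integral f dV` for spherical `f`.  `a` is the radial extent of the grid
#' in angstrom.
#'
#' @param n number of radial nodes (>= 10).
#' @param a radial extent (angstrom); nodes cover (0, a].
#' @param p power of the transform (>= 1); 3 by default.
#' @return a `radial_grid`: `r` (nodes, angstrom), `w` (weights including
#'   the r^2 measure), and the parameters.
#' @export
radial_grid <- function(n, a, p = 3) {
  stopifnot(n >= 10, a > 0, p >= 1)
  x <- (seq_len(n) - 0.5) / n
  r <- a * x^p
  w <- (1 / n) * p * a * x^(p - 1) * r^2
  structure(list(r = r, w = w, n = n, a = a, p = p), class = "radial_grid")
}

## per-element radial defaults: node counts from the carbon reference value,
## neighbours interpolated by period; extent scaled by Bragg-Slater radius.
.RADIAL_N <- c(H = 100L, C = 148L, N = 148L, O = 148L, P = 175L, S = 175L)

.radial_extent <- function(element)
  12 * (bragg_slater_radius(element) / 0.35)^(1/3)

## ---------------------------------------------------------------------
## Angular quadrature ladder.  Two exact octahedral rules (6- and 26-point)
## plus Gauss-Legendre(theta) x uniform(phi) product rules for the larger
## rungs; a rule of degree d integrates all spherical harmonics with
## l <= d exactly.  Rung sizes track the conventional ladder used for
## pruned atomic grids (capped at 1682 points, degree 57).
.ANGULAR_SIZES <- c(6L, 26L, 98L, 288L, 578L, 1152L, 1682L,
                    2450L, 4802L, 7938L)
.ANGULAR_DEGREES <- c(3L, 7L, 13L, 23L, 33L, 47L, 57L, 69L, 97L, 125L)

#' Angular quadrature grid on the unit sphere
#'
#' @param n_points requested rung size; rounded down to the nearest
#'   available rung of the ladder `c(6, 26, 98, 288, 578, 1152, 1682)`.
#' @return an `angular_grid`: `u` (n x 3 unit vectors), `w` (weights summing
#'   to 4 pi), `degree` (highest spherical-harmonic degree integrated
#'   exactly), `n`.
#' @export
angular_grid <- function(n_points) {
  sizes <- .ANGULAR_SIZES
  if (n_points < sizes[1]) stop("smallest angular rule has 6 points")
  k <- max(which(sizes <= n_points))
  size <- sizes[k]
  if (size == 6L) {
    u <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    w <- rep(4 * pi / 6, 6)
  } else if (size == 26L) {
    s2 <- 1 / sqrt(2); s3 <- 1 / sqrt(3)
    v1 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    perm2 <- rbind(c(s2, s2, 0), c(s2, -s2, 0), c(-s2, s2, 0), c(-s2, -s2, 0),
                   c(s2, 0, s2), c(s2, 0, -s2), c(-s2, 0, s2), c(-s2, 0, -s2),
                   c(0, s2, s2), c(0, s2, -s2), c(0, -s2, s2), c(0, -s2, -s2))
    corn <- as.matrix(expand.grid(c(-s3, s3), c(-s3, s3), c(-s3, s3)))
    u <- rbind(v1, perm2, corn)
    w <- 4 * pi * c(rep(1 / 21, 6), rep(4 / 105, 12), rep(27 / 840, 8))
  } else {
    ## product rule: n_theta Gauss-Legendre x 2 n_theta uniform phi
    nt <- c(`98` = 7L, `288` = 12L, `578` = 17L, `1152` = 24L,
            `1682` = 29L, `2450` = 35L, `4802` = 49L,
            `7938` = 63L)[[as.character(size)]]
    gl <- pracma::gaussLegendre(nt, -1, 1)
    np <- 2L * nt
    phi <- 2 * pi * (seq_len(np) - 0.5) / np
    ct <- rep(gl$x, each = np)
    st <- sqrt(pmax(0, 1 - ct^2))
    ph <- rep(phi, times = nt)
    u <- cbind(st * cos(ph), st * sin(ph), ct)
    w <- rep(gl$w, each = np) * (2 * pi / np)
  }
  dimnames(u) <- NULL
  structure(list(u = u, w = w, n = size,
                 degree = .ANGULAR_DEGREES[k]),
            class = "angular_grid")
}

## ---------------------------------------------------------------------
## Becke smoothed-cell weights

## the thrice-iterated smoothing polynomial f(mu) = mu(3 - mu^2)/2
.becke_smooth <- function(mu, k = 3L) {
  for (i in seq_len(k)) mu <- 0.5 * mu * (3 - mu^2)
  mu
}

#' Becke cell weights at arbitrary points
#'
#' Smoothed Voronoi partition of unity with atomic-size adjustment: for each
#' atom pair the elliptic coordinate `mu_ij = (r_i - r_j)/R_ij` is shifted by
#' `a_ij (1 - mu_ij^2)` with `a_ij` derived from the Bragg-Slater radius
#' ratio (clipped to |a_ij| <= 1/2), smoothed three times with
#' `f(mu) = mu(3 - mu^2)/2`, and turned into cell functions
#' `s = (1 - f)/2` whose normalised products give the weights.
#'
#' @param atom_cart n_atoms x 3 matrix of Cartesian positions (angstrom).
#' @param radii per-atom Bragg-Slater radii (angstrom).
#' @param points m x 3 matrix of probe points (angstrom).
#' @return m x n_atoms matrix of non-negative weights; each row sums to 1.
#' @export
becke_cell_weights <- function(atom_cart, radii, points) {
  atom_cart <- rbind3(atom_cart); points <- rbind3(points)
  n <- nrow(atom_cart)
  stopifnot(length(radii) == n, all(radii > 0))
  if (n == 1) return(matrix(1, nrow(points), 1))
  ## pairwise atom distances
  dd <- as.matrix(stats::dist(atom_cart))
  if (any(dd[upper.tri(dd)] < 1e-8)) stop("coincident atoms in Becke cells")
  ## distances point -> atom
  pd <- matrix(0, nrow(points), n)
  for (a in seq_len(n)) {
    dx <- sweep(points, 2, atom_cart[a, ])
    pd[, a] <- sqrt(rowSums(dx * dx))
  }
  P <- matrix(1, nrow(points), n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    mu <- (pd[, i] - pd[, j]) / dd[i, j]
    chi <- radii[i] / radii[j]
    uu <- (chi - 1) / (chi + 1)
    aij <- uu / (uu^2 - 1)
    aij <- max(min(aij, 0.5), -0.5)
    nu <- mu + aij * (1 - mu^2)
    P[, i] <- P[, i] * 0.5 * (1 - .becke_smooth(nu))
  }
  sw <- rowSums(P)
  sweep(P, 1, sw, "/")
}

## ---------------------------------------------------------------------
## Molecular grid

#' Per-element molecular grid specification
#'
#' @param n_radial named integer vector (per element) of radial node counts;
#'   missing elements fall back to the package defaults.
#' @param max_angular named or scalar maximum angular rung size.
#' @param radial_extent optional named numeric vector of radial extents (angstrom).
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(n_radial = NULL, max_angular = NULL,
                      radial_extent = NULL) {
  structure(list(n_radial = n_radial, max_angular = max_angular,
                 radial_extent = radial_extent),
            class = "grid_spec")
}

.spec_for_element <- function(spec, element) {
  pick <- function(x, default) {
    if (is.null(x)) return(default)
    if (!is.null(names(x))) {
      if (element %in% names(x)) return(x[[element]])
      return(default)
    }
    x[[1]]
  }
  list(n_radial = pick(spec$n_radial, .RADIAL_N[[element]]),
       max_angular = pick(spec$max_angular, 1682L),
       a = pick(spec$radial_extent, .radial_extent(element)))
}

## angular rung for one radial shell under the pruning schedule:
## small rung close to the nucleus, the maximum rung through the valence
## region, one rung down in the far tail.
.pruned_order <- function(r, r_bs, max_angular) {
  sizes <- .ANGULAR_SIZES[.ANGULAR_SIZES <= max_angular]
  kmax <- length(sizes)
  if (r < 0.3 * r_bs) sizes[min(2L, kmax)]
  else if (r <= 6 * r_bs) sizes[kmax]
  else sizes[max(1L, kmax - 1L)]
}

#' Build a Becke multicenter molecular grid
#'
#' Atom-centred power-transform radial grids crossed with angular rules
#' (optionally pruned near the nucleus and in the far tail), fused with
#' Becke smoothed-cell weights into a single quadrature rule for molecular
#' integrals.
#'
#' @param molecule a molecule (list with `elements` and `cart`) or a
#'   [crystal_structure()] (its asymmetric unit is used).
#' @param spec a [grid_spec()]; defaults give carbon 148 radial nodes and
#'   angular rungs capped at 1682 points.
#' @param prune logical; apply the angular pruning schedule.
#' @return a `molecular_grid`: `points` (n x 3, angstrom), `w` (total
#'   quadrature weights), `owner` (atom index per point), `radial_index`,
#'   `radial_r` (distance of the point's shell from its own nucleus),
#'   `w_angular` (bare angular weight of the point), `cell_w` (Becke cell
#'   weight of the owner at the point), `molecule`, `n_per_atom`.
#' @export
build_molecular_grid <- function(molecule, spec = grid_spec(), prune = TRUE) {
  mol <- as_molecule(molecule)
  n_atoms <- length(mol$elements)
  radii <- bragg_slater_radius(mol$elements)
  pts <- list(); wr <- list(); own <- list(); ridx <- list()
  rsh <- list(); wang <- list()
  ang_cache <- new.env(parent = emptyenv())
  get_ang <- function(size) {
    key <- as.character(size)
    if (is.null(ang_cache[[key]])) ang_cache[[key]] <- angular_grid(size)
    ang_cache[[key]]
  }
  for (a in seq_len(n_atoms)) {
    el <- mol$elements[a]
    es <- .spec_for_element(spec, el)
    rad <- radial_grid(es$n_radial, es$a)
    for (j in seq_len(rad$n)) {
      size <- if (prune) .pruned_order(rad$r[j], radii[a], es$max_angular)
              else utils::tail(.ANGULAR_SIZES[.ANGULAR_SIZES <= es$max_angular], 1)
      ang <- get_ang(size)
      p <- sweep(ang$u * rad$r[j], 2, mol$cart[a, ], "+")
      pts[[length(pts) + 1]] <- p
      wr[[length(wr) + 1]] <- rad$w[j] * ang$w
      own[[length(own) + 1]] <- rep.int(a, ang$n)
      ridx[[length(ridx) + 1]] <- rep.int(j, ang$n)
      rsh[[length(rsh) + 1]] <- rep.int(rad$r[j], ang$n)
      wang[[length(wang) + 1]] <- ang$w
    }
  }
  points <- do.call(rbind, pts)
  w_atomic <- unlist(wr)
  owner <- unlist(own)
  cell <- becke_cell_weights(mol$cart, radii, points)
  cell_w <- cell[cbind(seq_len(nrow(points)), owner)]
  structure(list(points = points, w = w_atomic * cell_w,
                 owner = owner, radial_index = unlist(ridx),
                 radial_r = unlist(rsh), w_angular = unlist(wang),
                 cell_w = cell_w, molecule = mol,
                 n_per_atom = tabulate(owner, n_atoms)),
            class = "molecular_grid")
}

#' @export
print.molecular_grid <- function(x, ...) {
  cat(sprintf("molecular grid: %d points over %d atom(s)\n",
              nrow(x$points), length(x$n_per_atom)))
  invisible(x)
}

#' Integrate sampled values on a molecular grid
#'
#' @param grid a `molecular_grid`.
#' @param values numeric vector of per-point samples.
#' @return the quadrature sum `sum(w * values)`.
#' @export
grid_integrate <- function(grid, values) {
  if (length(values) != nrow(grid$points))
    stop("values length (", length(values), ") does not match grid size (",
         nrow(grid$points), ")")
  if (!all(is.finite(values))) stop("non-finite values in integrand")
  sum(grid$w * values)
}

#' Coerce to a molecule (elements + Cartesian coordinates)
#'
#' @param x a list with `elements` and `cart`, or a [crystal_structure()]
#'   whose asymmetric unit is taken.
#' @return list with `elements` and `cart` (n x 3 matrix, angstrom).
#' @export
as_molecule <- function(x) {
  if (inherits(x, "crystal_structure")) {
    st <- site_table(x)
    return(list(elements = st$elements, cart = st$cart,
                labels = st$labels))
  }
  stopifnot(is.list(x), !is.null(x$elements), !is.null(x$cart))
  x$cart <- rbind3(x$cart)
  x
}
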