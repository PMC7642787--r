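## Crystal-structure container: atom sites (fractional coordinates +
## CIF-convention ADP tensors), verbatim symmetry-operator lists, and
## small helpers (bond detection, bond lengths).

#' Parse a symmetry operator string
#'
#' Accepts CIF `_symmetry_equiv_pos_as_xyz` strings such as
#' `"x, y, z"`, `"-x, -y, -z"` or `"1/2+x, 1/2-y, z"`.
#'
#' @param s a single operator string.
#' @return list with integer 3x3 `R` (fractional rotation) and numeric
#'   length-3 `t` (fractional translation in [0,1)).
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[ '\"]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", s)
  R <- matrix(0, 3, 3)
  tr <- numeric(3)
  axes <- c(x = 1L, y = 2L, z = 3L)
  for (i in 1:3) {
    expr <- parts[i]
    ## split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (body %in% names(axes)) {
        R[i, axes[body]] <- R[i, axes[body]] + sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        num <- as.numeric(strsplit(body, "/")[[1]])
        tr[i] <- tr[i] + sign * num[1] / num[2]
      } else if (grepl("^[0-9.]+$", body)) {
        tr[i] <- tr[i] + sign * as.numeric(body)
      } else stop("cannot parse symmetry term '", term, "' in: ", s)
    }
  }
  list(R = R, t = tr %% 1)
}

#' Format a symmetry operator as an xyz string
#' @param op list with `R` and `t` as returned by [parse_symop()].
#' @return character scalar like `"-x,1/2+y,-z"`.
#' @export
format_symop <- function(op) {
  axes <- c("x", "y", "z")
  out <- character(3)
  for (i in 1:3) {
    s <- ""
    ti <- op$t[i] %% 1
    if (abs(ti) > 1e-9) {
      fr <- c(`1/2` = 0.5, `1/3` = 1/3, `2/3` = 2/3,
              `1/4` = 0.25, `3/4` = 0.75, `1/6` = 1/6, `5/6` = 5/6)
      hit <- names(fr)[abs(fr - ti) < 1e-9]
      s <- if (length(hit)) hit[1] else format(ti)
    }
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r == 0) next
      s <- paste0(s, if (r > 0 && nzchar(s)) "+" else if (r < 0) "-" else "",
                  axes[j])
      if (abs(r) != 1) stop("non-unit rotation elements not supported")
    }
    out[i] <- s
  }
  paste(out, collapse = ",")
}

#' Construct an atom site
#'
#' @param label site label (kept verbatim through file round trips).
#' @param element element symbol.
#' @param frac_pos length-3 fractional coordinates.
#' @param u_cif symmetric 3x3 ADP tensor, CIF convention (angstrom^2).
#' @param occupancy site occupancy in (0, 1].
#' @return an `atom_site` list.
#' @export
atom_site <- function(label, element, frac_pos, u_cif = diag(0.01, 3),
                      occupancy = 1) {
  element <- as.character(element)
  atomic_number(element)  # validates
  stopifnot(length(frac_pos) == 3)
  u_cif <- as.matrix(u_cif)
  if (max(abs(u_cif - t(u_cif))) > 1e-10) stop("u_cif must be symmetric")
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0,1]")
  structure(list(label = as.character(label), element = element,
                 frac_pos = as.numeric(frac_pos), u_cif = u_cif,
                 occupancy = occupancy),
            class = "atom_site")
}

#' Construct a crystal structure
#'
#' @param cell a `unit_cell`.
#' @param sites list of `atom_site` objects.
#' @param symops list of symmetry operators ([parse_symop()] form) or
#'   character vector of xyz strings.  Defaults to P1.
#' @param wavelength optional radiation wavelength (angstrom).
#' @return a `crystal_structure`.
#' @export
crystal_structure <- function(cell, sites, symops = "x,y,z",
                              wavelength = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.character(symops)) symops <- lapply(symops, parse_symop)
  has_identity <- any(vapply(symops, function(op) {
    max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t %% 1)) < 1e-9
  }, logical(1)))
  if (!has_identity) stop("symmetry operator list must contain the identity")
  stopifnot(all(vapply(sites, inherits, logical(1), "atom_site")))
  structure(list(cell = cell, sites = sites, symops = symops,
                 wavelength = wavelength),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d site(s), %d symmetry operator(s)\n",
              length(x$sites), length(x$symops)))
  print(x$cell)
  for (s in x$sites)
    cat(sprintf("  %-5s %-2s  %8.5f %8.5f %8.5f  Ueq=%.4f occ=%.2f\n",
                s$label, s$element, s$frac_pos[1], s$frac_pos[2],
                s$frac_pos[3], u_equiv(s$u_cif, x$cell), s$occupancy))
  invisible(x)
}

#' Site properties as vectors/matrices
#' @param structure a `crystal_structure`.
#' @return list with `labels`, `elements`, `frac` (n x 3), `cart` (n x 3,
#'   angstrom), `occupancy`.
#' @export
site_table <- function(structure) {
  frac <- do.call(rbind, lapply(structure$sites, `[[`, "frac_pos"))
  list(labels = vapply(structure$sites, `[[`, character(1), "label"),
       elements = vapply(structure$sites, `[[`, character(1), "element"),
       frac = frac,
       cart = frac_to_cart(structure$cell, frac),
       occupancy = vapply(structure$sites, `[[`, numeric(1), "occupancy"))
}

#' Detect covalent bonds in the asymmetric unit
#'
#' Two sites are bonded when their Cartesian distance is below
#' `tol_scale * (r_cov_i + r_cov_j)`.  Only intra-asymmetric-unit bonds are
#' detected (no symmetry contacts).
#'
#' @param structure a `crystal_structure`.
#' @param tol_scale multiplier on the covalent-radius sum (default 1.2).
#' @return two-column matrix of site indices (i < j), possibly 0 rows.
#' @export
detect_bonds <- function(structure, tol_scale = 1.2) {
  st <- site_table(structure)
  n <- nrow(st$cart)
  out <- NULL
  if (n >= 2) {
    rc <- covalent_radius(st$elements)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((st$cart[i, ] - st$cart[j, ])^2))
      if (d < tol_scale * (rc[i] + rc[j])) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("i", "j")
  out
}

#' Bond lengths for index pairs
#' @param structure a `crystal_structure`.
#' @param bonds two-column index matrix as from [detect_bonds()].
#' @return numeric vector of bond lengths (angstrom).
#' @export
bond_lengths <- function(structure, bonds) {
  st <- site_table(structure)
  apply(bonds, 1, function(b)
    sqrt(sum((st$cart[b[1], ] - st$cart[b[2], ])^2)))
}
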