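## Minimal CIF 1.1 reader/writer for the subset the pipeline touches:
## cell, explicit symmetry-operator list, _atom_site loop and optional
## _atom_site_aniso loop.  Labels are preserved verbatim; numbers written
## at full precision so synthetic structures round-trip.

## strip a standard-uncertainty suffix "1.234(5)" -> 1.234
.cif_num <- function(x) as.numeric(sub("\\([0-9]+\\)$", "", x))

## tokenize a CIF line respecting single/double quotes
.cif_tokens <- function(line) {
  toks <- regmatches(line,
    gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

#' Read a crystal structure from a CIF file
#'
#' Supports the CIF 1.1 subset written by [write_cif()]: cell parameters,
#' an explicit `_symmetry_equiv_pos_as_xyz` loop (P1 assumed, with a
#' warning, when absent), an `_atom_site` loop and an optional
#' `_atom_site_aniso` loop.  Sites without an aniso entry get the
#' isotropic-equivalent tensor built from `_atom_site_U_iso_or_equiv`.
#'
#' @param path path to a CIF file.
#' @return a [crystal_structure()].
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  items <- list()   # scalar data items
  loops <- list()   # each: list(tags=..., rows=list of token vectors)
  i <- 1
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "data_")) { i <- i + 1; next }
    if (tolower(line) == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= n && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1
      }
      rows <- list()
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (!nzchar(l2) || startsWith(l2, "_") || tolower(l2) == "loop_" ||
            startsWith(l2, "data_")) break
        rows[[length(rows) + 1]] <- .cif_tokens(l2)
        i <- i + 1
      }
      loops[[length(loops) + 1]] <- list(tags = tags, rows = rows)
    } else if (startsWith(line, "_")) {
      toks <- .cif_tokens(line)
      if (length(toks) >= 2)
        items[[toks[1]]] <- paste(toks[-1], collapse = " ")
      i <- i + 1
    } else i <- i + 1
  }

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  if (!all(need %in% names(items)))
    stop("CIF is missing cell parameters (", path, ")")
  ang <- function(tag, default) if (tag %in% names(items))
    .cif_num(items[[tag]]) else default
  cell <- unit_cell(.cif_num(items[["_cell_length_a"]]),
                    .cif_num(items[["_cell_length_b"]]),
                    .cif_num(items[["_cell_length_c"]]),
                    ang("_cell_angle_alpha", 90),
                    ang("_cell_angle_beta", 90),
                    ang("_cell_angle_gamma", 90))

  find_loop <- function(tag_re) {
    for (lp in loops) if (any(grepl(tag_re, lp$tags))) return(lp)
    NULL
  }

  symops <- "x,y,z"
  symloop <- find_loop("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz")
  if (is.null(symloop)) {
    warning("CIF has no symmetry operator list; assuming P1")
  } else {
    k <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
              symloop$tags)[1]
    ## operator strings may have been split on whitespace when unquoted
    symops <- vapply(symloop$rows, function(r)
      paste(r[k:length(r)], collapse = ""), character(1))
  }

  siteloop <- find_loop("^_atom_site_label$")
  if (is.null(siteloop)) stop("CIF has no _atom_site loop (", path, ")")
  tags <- siteloop$tags
  col <- function(tag) match(tag, tags)
  ic_lab <- col("_atom_site_label")
  ic_el <- col("_atom_site_type_symbol")
  ic_x <- col("_atom_site_fract_x"); ic_y <- col("_atom_site_fract_y")
  ic_z <- col("_atom_site_fract_z")
  ic_occ <- col("_atom_site_occupancy")
  ic_uiso <- col("_atom_site_U_iso_or_equiv")

  aniso <- list()
  anloop <- find_loop("^_atom_site_aniso_label$")
  if (!is.null(anloop)) {
    at <- anloop$tags
    acol <- function(tag) match(tag, at)
    for (r in anloop$rows) {
      u <- matrix(0, 3, 3)
      u[1, 1] <- .cif_num(r[acol("_atom_site_aniso_U_11")])
      u[2, 2] <- .cif_num(r[acol("_atom_site_aniso_U_22")])
      u[3, 3] <- .cif_num(r[acol("_atom_site_aniso_U_33")])
      u[2, 3] <- u[3, 2] <- .cif_num(r[acol("_atom_site_aniso_U_23")])
      u[1, 3] <- u[3, 1] <- .cif_num(r[acol("_atom_site_aniso_U_13")])
      u[1, 2] <- u[2, 1] <- .cif_num(r[acol("_atom_site_aniso_U_12")])
      aniso[[r[acol("_atom_site_aniso_label")]]] <- u
    }
  }

  sites <- lapply(siteloop$rows, function(r) {
    lab <- r[ic_lab]
    el <- if (!is.na(ic_el)) r[ic_el] else gsub("[0-9']+.*$", "", lab)
    if (!el %in% .ELEMENTS)
      stop("unknown element symbol '", el, "' for site '", lab, "'")
    occ <- if (!is.na(ic_occ) && ic_occ <= length(r)) .cif_num(r[ic_occ]) else 1
    u <- aniso[[lab]]
    if (is.null(u)) {
      uiso <- if (!is.na(ic_uiso) && ic_uiso <= length(r))
        .cif_num(r[ic_uiso]) else 0.01
      u <- u_iso_to_cif(uiso, cell)
    }
    atom_site(lab, el, c(.cif_num(r[ic_x]), .cif_num(r[ic_y]),
                         .cif_num(r[ic_z])), u, occ)
  })

  crystal_structure(cell, sites, symops)
}

#' Write a crystal structure to a CIF file
#'
#' @param structure a [crystal_structure()].
#' @param path output path.
#' @param data_name CIF data-block name.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path, data_name = "gar") {
  cell <- structure$cell
  fmt <- function(x) sprintf("%.12g", x)
  out <- c(
    paste0("data_", data_name),
    paste("_cell_length_a", fmt(cell$a)),
    paste("_cell_length_b", fmt(cell$b)),
    paste("_cell_length_c", fmt(cell$c)),
    paste("_cell_angle_alpha", fmt(cell$alpha)),
    paste("_cell_angle_beta", fmt(cell$beta)),
    paste("_cell_angle_gamma", fmt(cell$gamma)),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(structure$symops, function(op)
      paste0("'", format_symop(op), "'"), character(1)),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_U_iso_or_equiv",
    "_atom_site_occupancy",
    vapply(structure$sites, function(s)
      paste(s$label, s$element, fmt(s$frac_pos[1]), fmt(s$frac_pos[2]),
            fmt(s$frac_pos[3]), fmt(u_equiv(s$u_cif, cell)),
            fmt(s$occupancy)), character(1)),
    "loop_",
    "_atom_site_aniso_label",
    "_atom_site_aniso_U_11",
    "_atom_site_aniso_U_22",
    "_atom_site_aniso_U_33",
    "_atom_site_aniso_U_23",
    "_atom_site_aniso_U_13",
    "_atom_site_aniso_U_12",
    vapply(structure$sites, function(s)
      paste(s$label, fmt(s$u_cif[1, 1]), fmt(s$u_cif[2, 2]),
            fmt(s$u_cif[3, 3]), fmt(s$u_cif[2, 3]), fmt(s$u_cif[1, 3]),
            fmt(s$u_cif[1, 2])), character(1)))
  writeLines(out, path)
  invisible(path)
}
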