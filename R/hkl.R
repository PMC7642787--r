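## SHELX HKLF-4 reflection files: fixed-width `3I4, 2F8` records of
## h k l F_o^2 sigma(F_o^2); the 0 0 0 terminator line is honoured.

#' Construct a reflection set
#'
#' @param hkl integer matrix (n x 3) of Miller indices.
#' @param f_obs_sq numeric vector of observed intensities (F_o^2,
#'   arbitrary scale).
#' @param sigma numeric vector of standard uncertainties of F_o^2.
#' @param cell optional `unit_cell` used to attach d-spacings.
#' @return a `reflection_set` with logical `usable` (sigma > 0) and, when a
#'   cell is given, per-reflection `resolution` in angstrom.
#' @export
reflection_set <- function(hkl, f_obs_sq, sigma, cell = NULL) {
  hkl <- rbind3(hkl)
  storage.mode(hkl) <- "integer"
  stopifnot(nrow(hkl) == length(f_obs_sq), length(f_obs_sq) == length(sigma))
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) stop("hkl must be unique after merging")
  res <- if (!is.null(cell)) d_spacing(cell, hkl) else rep(NA_real_, nrow(hkl))
  structure(list(hkl = hkl, f_obs_sq = as.numeric(f_obs_sq),
                 sigma = as.numeric(sigma), usable = sigma > 0,
                 resolution = res),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set: %d reflections (%d usable)",
              nrow(x$hkl), sum(x$usable)))
  if (!all(is.na(x$resolution)))
    cat(sprintf(", d in [%.3f, %.3f] A", min(x$resolution), max(x$resolution)))
  cat("\n")
  invisible(x)
}

#' Read a SHELX HKLF-4 reflection file
#'
#' Duplicate measurements of the same index are merged by inverse-variance
#' weighted mean with the combined sigma; reflections with sigma <= 0 are
#' retained but flagged unusable.
#'
#' @param path path to a fixed-width `.hkl` file.
#' @param cell optional `unit_cell` for resolution annotation.
#' @return a [reflection_set()].
#' @export
read_hkl <- function(path, cell = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- matrix(NA_real_, length(lines), 5)
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (nchar(l) < 28) l <- formatC(l, width = -28)
    f <- suppressWarnings(as.numeric(c(substr(l, 1, 4), substr(l, 5, 8),
                                       substr(l, 9, 12), substr(l, 13, 20),
                                       substr(l, 21, 28))))
    if (anyNA(f[1:3]))
      stop("malformed .hkl line ", i, ": '", lines[i], "'")
    if (all(f[1:3] == 0)) break  # HKLF terminator
    if (anyNA(f[4:5]))
      stop("malformed .hkl line ", i, ": '", lines[i], "'")
    recs[i, ] <- f
  }
  recs <- recs[stats::complete.cases(recs), , drop = FALSE]
  if (nrow(recs) == 0) stop("no reflections in ", path)
  key <- paste(recs[, 1], recs[, 2], recs[, 3])
  merged <- lapply(split(seq_len(nrow(recs)), key), function(idx) {
    sub <- recs[idx, , drop = FALSE]
    if (nrow(sub) == 1) return(sub[1, ])
    w <- 1 / sub[, 5]^2
    c(sub[1, 1:3], sum(w * sub[, 4]) / sum(w), sqrt(1 / sum(w)))
  })
  m <- do.call(rbind, merged)
  ## keep stable original order of first occurrence
  ord <- order(match(rownames(m), unique(key)))
  m <- m[ord, , drop = FALSE]
  dimnames(m) <- NULL
  reflection_set(m[, 1:3, drop = FALSE], m[, 4], m[, 5], cell = cell)
}

#' Write a reflection set as SHELX HKLF-4
#'
#' @param refl a [reflection_set()].
#' @param path output path.
#' @param terminator write the conventional `0 0 0` end record.
#' @return `path`, invisibly.
#' @export
write_hkl <- function(refl, path, terminator = TRUE) {
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f",
                   refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3],
                   refl$f_obs_sq, refl$sigma)
  too_wide <- nchar(lines) > 28
  if (any(too_wide))
    stop("intensity out of range for fixed-width HKLF-4 output (",
         sum(too_wide), " reflections); rescale first")
  if (terminator)
    lines <- c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0))
  writeLines(lines, path)
  invisible(path)
}
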