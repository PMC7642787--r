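## XYZ files (element x y z in angstrom) for isolated-molecule input and
## debug dumps.

#' Read an XYZ file
#' @param path path to an XYZ file (count line, comment line, then
#'   `element x y z` records in angstrom).
#' @return list with `elements` (character) and `cart` (n x 3 matrix, angstrom).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ header in ", path)
  rows <- lines[3:(2 + n)]
  toks <- lapply(strsplit(trimws(rows), "\\s+"), function(t) t[1:4])
  elements <- vapply(toks, `[`, character(1), 1)
  cart <- do.call(rbind, lapply(toks, function(t) as.numeric(t[2:4])))
  if (anyNA(cart)) stop("malformed XYZ coordinates in ", path)
  list(elements = elements, cart = cart)
}

#' Write an XYZ file
#' @param elements character vector of element symbols.
#' @param cart n x 3 matrix of Cartesian coordinates (angstrom).
#' @param path output path.
#' @param comment comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(elements, cart, path, comment = "") {
  cart <- rbind3(cart)
  stopifnot(length(elements) == nrow(cart))
  writeLines(c(length(elements), comment,
               sprintf("%-2s %18.10f %18.10f %18.10f",
                       elements, cart[, 1], cart[, 2], cart[, 3])), path)
  invisible(path)
}
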