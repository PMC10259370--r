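# Standard XYZ file I/O: atom-count line, comment line, then one
# "element x y z" line per atom. Always UTF-8, coordinates in Angstrom.

#' Write coordinates to an XYZ file
#'
#' @param x A `qc_structure` (see [embed_3d()]) or a list with `elements`
#'   (character) and `coords` (numeric n-by-3 matrix).
#' @param path Output file path.
#' @param comment Single comment line (default records charge/multiplicity
#'   for structures).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = NULL) {
  if (inherits(x, "qc_structure")) {
    elements <- x$graph$atoms$element
    coords <- x$coords
    if (is.null(comment)) {
      comment <- sprintf("charge=%d multiplicity=%d", x$charge, x$multiplicity)
    }
  } else {
    elements <- x$elements
    coords <- x$coords
    if (is.null(comment)) comment <- ""
  }
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) == length(elements))
  lines <- c(
    as.character(length(elements)),
    comment,
    sprintf("%-3s %14.6f %14.6f %14.6f",
            elements, coords[, 1], coords[, 2], coords[, 3])
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path Path to an XYZ file.
#' @return A list with `elements`, `coords` (n-by-3 matrix, Angstrom) and
#'   `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("not an XYZ file: fewer than two lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("not an XYZ file: first line must be the atom count")
  if (length(lines) < 2L + n) stop("XYZ file truncated: expected ", n, " atom lines")
  comment <- lines[2]
  fields <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  elements <- vapply(fields, `[[`, character(1), 1)
  coords <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (anyNA(coords)) stop("XYZ file contains non-numeric coordinates")
  list(elements = elements, coords = coords, comment = comment)
}
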