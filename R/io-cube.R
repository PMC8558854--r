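## Gaussian cube and flat-TSV export of catalytic-field grids.

ELEMENT_Z <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, NA_ = 11L, MG = 12L,
               P = 15L, S = 16L, CL = 17L, K = 19L, CA = 20L, ZN = 30L)

element_number <- function(el) {
  z <- ELEMENT_Z[toupper(ifelse(is.na(el), "", el))]
  as.integer(ifelse(is.na(z), 6L, z))  # unknown/dummy centers drawn as carbon
}

#' Write a catalytic-field grid as a Gaussian cube file
#'
#' Header lengths are in bohr as the cube format requires; the data
#' section holds `Delta_S` in kcal/(mol e) with the z index fastest.
#' Masked nodes are written as `0.0` (the format has no missing-value
#' representation); use [write_field_tsv()] to preserve the mask. The atom
#' block lists the union of the RS and TS expansion centers with their
#' monopoles in the charge column. Output is byte-deterministic.
#'
#' @param grid a [static_field()] grid.
#' @param pair the [species_pair()] the grid was computed from (for the
#'   atom block); may be `NULL` to omit atoms.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, pair, path) {
  if (!inherits(grid, "field_grid")) abort("`grid` must be a field_grid.")
  origin_b <- attr(grid, "origin") * BOHR_PER_ANGSTROM
  spacing_b <- attr(grid, "spacing") * BOHR_PER_ANGSTROM
  shape <- attr(grid, "shape")
  atoms <- if (is.null(pair)) {
    tibble(z = integer(), q = numeric(), x = numeric(), y = numeric(), zz = numeric())
  } else {
    both <- bind_multipole_sets(pair$rs, pair$ts, fragment_id = "RS+TS")
    cm <- center_matrix(both)
    tibble(z = element_number(both$element), q = both$m0,
           x = cm[, 1], y = cm[, 2], zz = cm[, 3])
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con, sep = "\n")
  wl("catfield catalytic field Delta_S, kcal/(mol e)")
  wl("masked near-center nodes written as 0.0; z index fastest")
  wl("%5d%12.6f%12.6f%12.6f", nrow(atoms), origin_b[1], origin_b[2], origin_b[3])
  wl("%5d%12.6f%12.6f%12.6f", shape[1], spacing_b, 0, 0)
  wl("%5d%12.6f%12.6f%12.6f", shape[2], 0, spacing_b, 0)
  wl("%5d%12.6f%12.6f%12.6f", shape[3], 0, 0, spacing_b)
  for (i in seq_len(nrow(atoms))) {
    wl("%5d%12.6f%12.6f%12.6f%12.6f", atoms$z[i], atoms$q[i],
       atoms$x[i], atoms$y[i], atoms$zz[i])
  }
  vals <- grid$delta_s
  vals[is.na(vals)] <- 0
  ## rows of static_field() are already in cube order (z fastest)
  lines <- vapply(split(vals, ceiling(seq_along(vals) / 6)),
                  function(v) paste(sprintf("%16.8E", v), collapse = ""), "")
  writeLines(lines[order(as.integer(names(lines)))], con, sep = "\n")
  invisible(path)
}

#' Read a Gaussian cube file back into a field grid
#'
#' @param path path to a cube file with an orthogonal axis-aligned grid.
#' @return a `field_grid` tibble (coordinates converted to angstrom, no
#'   mask information); atom block returned in attribute `"atoms"`.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path)
  parse_nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr3 <- parse_nums(lines[3])
  natoms <- as.integer(hdr3[1]); origin_b <- hdr3[2:4]
  ax <- lapply(4:6, function(i) parse_nums(lines[i]))
  shape <- vapply(ax, function(a) as.integer(a[1]), 1L)
  vecs <- t(vapply(ax, function(a) a[2:4], numeric(3)))
  offdiag <- vecs; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-10) || length(unique(signif(diag(vecs), 10))) != 1) {
    abort(sprintf("%s: only axis-aligned cubic grids are supported.", path))
  }
  spacing_b <- vecs[1, 1]
  atom_lines <- lines[seq_len(natoms) + 6]
  atoms <- if (natoms > 0) {
    am <- t(vapply(atom_lines, parse_nums, numeric(5)))
    tibble(z = as.integer(am[, 1]), q = am[, 2],
           x = am[, 3], y = am[, 4], zz = am[, 5])
  } else tibble()
  vals <- unlist(lapply(lines[-seq_len(6 + natoms)], parse_nums), use.names = FALSE)
  if (length(vals) != prod(shape)) {
    abort(sprintf("%s: %d values for a %s grid.", path, length(vals),
                  paste(shape, collapse = "x")))
  }
  origin <- origin_b * ANGSTROM_PER_BOHR
  spacing <- spacing_b * ANGSTROM_PER_BOHR
  nodes <- expand.grid(
    iz = seq_len(shape[3]) - 1L,
    iy = seq_len(shape[2]) - 1L,
    ix = seq_len(shape[1]) - 1L
  )[, c("ix", "iy", "iz")]
  out <- tibble(x = origin[1] + nodes$ix * spacing,
                y = origin[2] + nodes$iy * spacing,
                z = origin[3] + nodes$iz * spacing,
                delta_s = vals, masked = FALSE)
  grid <- new_field_grid(out, origin = origin, spacing = spacing, shape = shape)
  attr(grid, "atoms") <- atoms
  grid
}

#' Write a field grid as a flat TSV
#'
#' Columns `x`, `y`, `z` (angstrom) and `delta_s` (kcal/(mol e); `NA` for
#' masked nodes). Byte-deterministic.
#'
#' @param grid a [static_field()] grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_tsv <- function(grid, path) {
  if (!inherits(grid, "field_grid")) abort("`grid` must be a field_grid.")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("x\ty\tz\tdelta_s", con, sep = "\n")
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.10g", v))
  writeLines(paste(sprintf("%.6f", grid$x), sprintf("%.6f", grid$y),
                   sprintf("%.6f", grid$z), fmt(grid$delta_s), sep = "\t"),
             con, sep = "\n")
  invisible(path)
}
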