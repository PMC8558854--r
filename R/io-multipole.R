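## Native multipole-file and rotamer-library formats (JSON).
##
## Multipole file (format "catfield-multipole-1"):
##   {
##     "format": "catfield-multipole-1",
##     "fragment_id": "RS",
##     "formal_charge": 0,            # optional
##     "units": {"length": "angstrom", "moments": "e_bohr^k"},   # mandatory
##     "atoms": [
##       {"label": "O1", "element": "O", "xyz": [x, y, z],
##        "moments": {"rank0": [1 value], "rank1": [3], "rank2": [6],
##                    "rank3": [10], "rank4": [15]}}
##     ]
##   }
## Moment components are the symmetric-unique components in lexicographic
## index order (xx, xy, xz, yy, yz, zz, ...). Numbers are written with 17
## significant digits so write -> read round-trips are bit-exact.
##
## CAMM-producing quantum-chemistry output (e.g. a GAMESS $ELMOM punch) is
## converted to this format externally; this file is the interchange point.

RANK_SIZES <- c(rank0 = 1L, rank1 = 3L, rank2 = 6L, rank3 = 10L, rank4 = 15L)

fmt_num <- function(x) sprintf("%.17g", x)

json_num_array <- function(x) paste0("[", paste(fmt_num(x), collapse = ", "), "]")

atom_records_json <- function(m, indent = "    ") {
  centers <- center_matrix(m) * ANGSTROM_PER_BOHR
  mom <- moment_matrix(m)
  recs <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    ranks <- vapply(MOMENT_RANKS, function(k) {
      idx <- rank_offset(k) + seq_len(n_unique(k))
      sprintf('"rank%d": %s', k, json_num_array(mom[i, idx]))
    }, "")
    el <- if (is.na(m$element[i])) "null" else sprintf('"%s"', m$element[i])
    recs[i] <- paste0(
      indent, "{\n",
      indent, sprintf('  "label": "%s", "element": %s,\n', m$label[i], el),
      indent, sprintf('  "xyz": %s,\n', json_num_array(centers[i, ])),
      indent, '  "moments": {', paste(ranks, collapse = ", "), "}\n",
      indent, "}")
  }
  paste(recs, collapse = ",\n")
}

#' Write a multipole set to the native JSON format
#'
#' Coordinates are written in angstrom and moments in e bohr^k, the
#' conventions of the file format; the writer is deterministic (identical
#' inputs give byte-identical files) and round-trips bit-exactly through
#' [read_multipole_file()].
#'
#' @param m a [multipole_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multipole_file <- function(m, path) {
  assert_multipole_set(m)
  fc <- attr(m, "formal_charge")
  hdr <- paste0(
    "{\n",
    '  "format": "catfield-multipole-1",\n',
    sprintf('  "fragment_id": "%s",\n', fragment_id(m)),
    if (!is.null(fc)) sprintf('  "formal_charge": %d,\n', as.integer(fc)) else "",
    '  "units": {"length": "angstrom", "moments": "e_bohr^k"},\n',
    '  "atoms": [\n')
  txt <- paste0(hdr, atom_records_json(m), "\n  ]\n}\n")
  writeLines(txt, path, sep = "")
  invisible(path)
}

parse_atom_records <- function(atoms, context) {
  n <- length(atoms)
  mcols <- moment_col_names_all()
  mom <- matrix(0, n, length(mcols), dimnames = list(NULL, mcols))
  label <- character(n); element <- character(n)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- atoms[[i]]
    label[i] <- a$label %||% abort(sprintf("%s: atom %d lacks a label.", context, i))
    element[i] <- a$element %||% NA_character_
    if (length(a$xyz) != 3) abort(sprintf("%s: atom %s has malformed xyz.", context, label[i]))
    xyz[i, ] <- as.numeric(a$xyz)
    col <- 1L
    for (k in MOMENT_RANKS) {
      comp <- a$moments[[paste0("rank", k)]]
      want <- RANK_SIZES[[paste0("rank", k)]]
      if (is.null(comp)) comp <- numeric(want)
      if (length(comp) != want) {
        abort(sprintf(
          "%s: atom %s declares %d rank-%d components; expected %d.",
          context, label[i], length(comp), k, want))
      }
      mom[i, col:(col + want - 1L)] <- as.numeric(comp)
      col <- col + want
    }
  }
  out <- as_tibble(as.data.frame(mom))
  out$label <- label; out$element <- element
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}

#' Read a multipole set from the native JSON format
#'
#' @param path path to a file written by [write_multipole_file()] (or by
#'   an external converter producing the same format).
#' @return a [multipole_set()] (coordinates converted to bohr).
#' @export
read_multipole_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$units) || is.null(doc$units$length)) {
    abort(sprintf("%s: mandatory units declaration is missing.", path))
  }
  if (!identical(doc$units$length, "angstrom")) {
    abort(sprintf("%s: unsupported length unit \"%s\".", path, doc$units$length))
  }
  atoms <- parse_atom_records(doc$atoms, context = path)
  multipole_set(atoms,
                fragment_id = doc$fragment_id %||% "fragment",
                formal_charge = doc$formal_charge,
                units = "angstrom")
}

## ---- Rotamer library format -------------------------------------------

#' Write a rotamer library to JSON
#'
#' Format "catfield-rotamers-1": per residue type, the anchor labels and a
#' list of rotamers, each with the same atom records as the multipole
#' format (coordinates angstrom, moments e bohr^k).
#'
#' @param library a [rotamer_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rotamer_library <- function(library, path) {
  anchors <- attr(library, "anchors")
  blocks <- character()
  for (tp in unique(library$type)) {
    sub <- library[library$type == tp, ]
    rots <- vapply(seq_len(nrow(sub)), function(r) {
      paste0('      {"id": "', sub$rotamer_id[r], '", "atoms": [\n',
             atom_records_json(sub$atoms[[r]], indent = "        "),
             "\n      ]}")
    }, "")
    blocks <- c(blocks, paste0(
      '    "', tp, '": {\n',
      '      "anchors": [', paste0('"', anchors[[tp]], '"', collapse = ", "), "],\n",
      '      "rotamers": [\n', paste(rots, collapse = ",\n"), "\n    ]}"))
  }
  txt <- paste0(
    "{\n",
    '  "format": "catfield-rotamers-1",\n',
    '  "units": {"length": "angstrom", "moments": "e_bohr^k"},\n',
    '  "types": {\n', paste(blocks, collapse = ",\n"), "\n  }\n}\n")
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Read a rotamer library from JSON
#'
#' @param path path to a file in the format of [write_rotamer_library()].
#' @return a [rotamer_library()].
#' @export
read_rotamer_library <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$units) || !identical(doc$units$length, "angstrom")) {
    abort(sprintf("%s: mandatory angstrom units declaration is missing.", path))
  }
  rows <- list(); anchors <- list()
  for (tp in names(doc$types)) {
    blk <- doc$types[[tp]]
    anchors[[tp]] <- unlist(blk$anchors)
    for (rot in blk$rotamers) {
      atoms <- parse_atom_records(rot$atoms, context = sprintf("%s (%s/%s)", path, tp, rot$id))
      rows[[length(rows) + 1L]] <- tibble(
        type = tp, rotamer_id = as.character(rot$id),
        atoms = list(multipole_set(atoms, fragment_id = paste0(tp, ":", rot$id),
                                   units = "angstrom")))
    }
  }
  rotamer_library(dplyr::bind_rows(rows), anchors)
}

## ---- Residue-site format ----------------------------------------------

#' Write residue sites to JSON
#'
#' @param sites a site tibble ([residue_site()] rows); anchor coordinates
#'   are written in angstrom.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_json <- function(sites, path) {
  sites <- as_tibble(sites)
  recs <- vapply(seq_len(nrow(sites)), function(i) {
    anc <- sites$anchors[[i]]
    arecs <- vapply(seq_len(nrow(anc)), function(j) {
      sprintf('      {"atom": "%s", "xyz": %s}', anc$atom[j],
              json_num_array(c(anc$x[j], anc$y[j], anc$z[j])))
    }, "")
    cr <- sites$crystal_rotamer[i]
    paste0(
      "  {\n",
      sprintf('    "site_id": "%s", "type": "%s",\n', sites$site_id[i], sites$type[i]),
      sprintf('    "chain": %s, "resno": %s,\n',
              if (is.na(sites$chain[i])) "null" else sprintf('"%s"', sites$chain[i]),
              if (is.na(sites$resno[i])) "null" else sites$resno[i]),
      sprintf('    "formal_charge": %d,\n', sites$formal_charge[i]),
      sprintf('    "crystal_rotamer": %s,\n',
              if (is.na(cr)) "null" else sprintf('"%s"', cr)),
      '    "anchors": [\n', paste(arecs, collapse = ",\n"), "\n    ]\n  }")
  }, "")
  writeLines(paste0("[\n", paste(recs, collapse = ",\n"), "\n]\n"), path, sep = "")
  invisible(path)
}

#' Read residue sites from JSON
#'
#' @param path path to a file written by [write_sites_json()].
#' @return a site tibble.
#' @export
read_sites_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(doc, function(s) {
    anc <- dplyr::bind_rows(lapply(s$anchors, function(a) {
      tibble(atom = a$atom, x = a$xyz[[1]], y = a$xyz[[2]], z = a$xyz[[3]])
    }))
    residue_site(type = s$type, anchors = anc, site_id = s$site_id,
                 chain = s$chain %||% NA_character_,
                 resno = s$resno %||% NA_integer_,
                 formal_charge = s$formal_charge %||% 0L,
                 crystal_rotamer = s$crystal_rotamer %||% NA_character_)
  })
  dplyr::bind_rows(rows)
}
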