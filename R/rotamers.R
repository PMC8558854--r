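## Rotamer libraries and rigid placement of side-chain multipoles.

#' Construct a rotamer library
#'
#' A rotamer library holds, per residue type, a set of discrete side-chain
#' conformations in a local frame: atom coordinates plus per-atom multipole
#' moments. Placement into a structure is a rigid transform determined by
#' superposing the type's anchor atoms onto their counterparts at a residue
#' site.
#'
#' @param rotamers data frame with columns `type` (residue type), and
#'   `rotamer_id`, and a list-column `atoms` of [multipole_set()] objects
#'   in the local frame (coordinates in bohr).
#' @param anchors named list: residue type -> character vector of anchor
#'   atom labels (at least three, non-collinear in every rotamer).
#' @return a tibble of class `rotamer_library` with attribute `anchors`.
#' @export
rotamer_library <- function(rotamers, anchors) {
  rotamers <- as_tibble(rotamers)
  if (!all(c("type", "rotamer_id", "atoms") %in% names(rotamers))) {
    abort("`rotamers` needs columns type, rotamer_id, atoms.")
  }
  rotamers$type <- as.character(rotamers$type)
  rotamers$rotamer_id <- as.character(rotamers$rotamer_id)
  for (tp in unique(rotamers$type)) {
    rows <- which(rotamers$type == tp)
    if (anyDuplicated(rotamers$rotamer_id[rows])) {
      abort(sprintf("Duplicate rotamer ids for type %s.", tp))
    }
    labelsets <- lapply(rows, function(r) sort(rotamers$atoms[[r]]$label))
    if (length(unique(labelsets)) != 1) {
      abort(sprintf("Rotamers of type %s differ in atom labels.", tp))
    }
    anc <- anchors[[tp]]
    if (is.null(anc) || length(anc) < 3) {
      abort(sprintf("Type %s needs at least three anchor labels.", tp))
    }
    if (!all(anc %in% labelsets[[1]])) {
      abort(sprintf("Anchor atoms missing from rotamers of type %s.", tp))
    }
  }
  structure(rotamers, anchors = anchors,
            class = c("rotamer_library", class(tibble())))
}

#' @export
print.rotamer_library <- function(x, ...) {
  counts <- table(x$type)
  cat("<rotamer_library>", length(counts), "residue types:\n")
  for (tp in names(counts)) {
    cat("  ", tp, ":", counts[[tp]], "rotamers, anchors",
        paste(attr(x, "anchors")[[tp]], collapse = "/"), "\n")
  }
  invisible(x)
}

library_anchors <- function(library, type) {
  anc <- attr(library, "anchors")[[type]]
  if (is.null(anc)) abort(sprintf("No anchors defined for residue type %s.", type))
  anc
}

library_rotamers <- function(library, type) {
  sub <- library[library$type == type, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("Rotamer library has no entries for residue type %s.", type),
          class = "catfield_empty_library")
  }
  sub
}

#' Describe a residue site
#'
#' @param type residue type matching a rotamer-library entry.
#' @param anchors data frame with columns `atom`, `x`, `y`, `z`: the
#'   anchor-atom coordinates observed in the structure (angstrom).
#' @param site_id unique site identifier (e.g. `"Glu83"`).
#' @param chain,resno optional chain id and residue number.
#' @param formal_charge formal side-chain charge (e).
#' @param crystal_rotamer optional id of the library rotamer closest to the
#'   crystallographic conformation.
#' @return a one-row tibble; combine sites with [dplyr::bind_rows()].
#' @export
residue_site <- function(type, anchors, site_id, chain = NA_character_,
                         resno = NA_integer_, formal_charge = 0L,
                         crystal_rotamer = NA_character_) {
  anchors <- as_tibble(anchors)
  if (!all(c("atom", "x", "y", "z") %in% names(anchors))) {
    abort("`anchors` needs columns atom, x, y, z.")
  }
  tibble(site_id = as.character(site_id), chain = chain,
         resno = as.integer(resno), type = as.character(type),
         formal_charge = as.integer(formal_charge),
         crystal_rotamer = as.character(crystal_rotamer),
         anchors = list(anchors))
}

#' Place a library rotamer at a residue site
#'
#' Superposes the rotamer's anchor atoms onto the site's anchor
#' coordinates ([superpose()]) and applies the resulting rigid transform
#' to the rotamer's coordinates and to every moment tensor (rotation via
#' [rotate_moments()] internals). The anchor RMSD after placement is
#' attached so sloppy anchor geometry is visible.
#'
#' @param site a one-row site tibble from [residue_site()].
#' @param rotamer_id id of the rotamer to place.
#' @param library a [rotamer_library()].
#' @return a [multipole_set()] in the site frame, fragment id
#'   `"<site_id>:<rotamer_id>"`, with attribute `anchor_rmsd` (angstrom).
#' @export
place_rotamer <- function(site, rotamer_id, library) {
  site <- as_tibble(site)
  if (nrow(site) != 1) abort("`site` must be a single site row.")
  sub <- library_rotamers(library, site$type)
  row <- which(sub$rotamer_id == as.character(rotamer_id))
  if (length(row) != 1) {
    abort(sprintf("Rotamer %s not found for type %s.", rotamer_id, site$type))
  }
  rot_set <- sub$atoms[[row]]
  anc <- library_anchors(library, site$type)
  local_xyz <- center_matrix(rot_set) * ANGSTROM_PER_BOHR
  mobile <- coord_set(tibble(atom = rot_set$label,
                             x = local_xyz[, 1], y = local_xyz[, 2], z = local_xyz[, 3]))
  reference <- coord_set(site$anchors[[1]])
  sup <- superpose(mobile, reference,
                   mapping = data.frame(mobile = anc, reference = anc))
  placed <- transform_multipole_set(rot_set, rotation = sup$rotation,
                                    translation = sup$translation * BOHR_PER_ANGSTROM)
  attr(placed, "fragment_id") <- paste0(site$site_id, ":", rotamer_id)
  attr(placed, "anchor_rmsd") <- sup$rmsd
  placed
}
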