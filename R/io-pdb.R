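## PDB reading (via bio3d) with the altloc/occupancy policy applied.

#' Read coordinates from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb()` that returns a tidy [coord_set()].
#' Alternate locations are resolved to the highest-occupancy copy (first
#' wins on ties); insertion codes are carried through untouched.
#'
#' @param path path to a PDB file.
#' @param selection optional list filter with any of `chain`, `resno`,
#'   `resid`, `atom` (each a vector of allowed values), applied after
#'   altloc resolution.
#' @param hetatm include HETATM records? Default `TRUE`.
#' @return a [coord_set()] with columns `chain`, `resno`, `insert`,
#'   `resid`, `atom`, `element`, `x`, `y`, `z`, `occupancy`.
#' @export
read_pdb <- function(path, selection = NULL, hetatm = TRUE) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) abort(sprintf("Failed to parse %s: %s",
                                                    path, conditionMessage(e))))
  at <- as_tibble(pdb$atom)
  if (!hetatm) at <- at[at$type == "ATOM", ]
  at$o[is.na(at$o)] <- 1
  at$insert[is.na(at$insert)] <- ""
  ## altloc policy: keep the highest-occupancy alternative per atom
  at <- dplyr::arrange(at, .data$chain, .data$resno, .data$insert, .data$elety,
                       dplyr::desc(.data$o))
  at <- dplyr::distinct(at, .data$chain, .data$resno, .data$insert, .data$elety,
                        .keep_all = TRUE)
  out <- tibble(chain = at$chain, resno = as.integer(at$resno),
                insert = at$insert, resid = at$resid, atom = at$elety,
                element = at$elesy, x = at$x, y = at$y, z = at$z,
                occupancy = at$o)
  if (!is.null(selection)) {
    for (field in intersect(names(selection), c("chain", "resno", "resid", "atom"))) {
      out <- out[out[[field]] %in% selection[[field]], ]
    }
  }
  coord_set(out)
}

#' Derive residue sites for MULTISCAN from a coordinate set
#'
#' Builds [residue_site()] rows for (by default) the charged residue types
#' with rotamer-library coverage, using the given anchor atom names.
#'
#' @param coords a [coord_set()] from [read_pdb()].
#' @param anchors named list: residue type -> anchor atom names expected
#'   in both the structure and the rotamer library.
#' @param types residue types to extract; default `names(anchors)`.
#' @param formal_charges named integer vector of side-chain formal charges
#'   per type (defaults: ASP/GLU -1, ARG/LYS +1, otherwise 0).
#' @return a site tibble; residues missing an anchor atom are skipped with
#'   a warning.
#' @export
residue_sites_from_coords <- function(coords, anchors, types = names(anchors),
                                      formal_charges = NULL) {
  tab <- as_tibble(coords)
  defaults <- c(ASP = -1L, GLU = -1L, ARG = 1L, LYS = 1L)
  rows <- list()
  resis <- dplyr::distinct(tab[toupper(tab$resid) %in% toupper(types), ],
                           .data$chain, .data$resno, .data$resid)
  for (i in seq_len(nrow(resis))) {
    tp <- toupper(resis$resid[i])
    anc_names <- anchors[[tp]]
    sub <- tab[tab$chain == resis$chain[i] & tab$resno == resis$resno[i] &
                 tab$atom %in% anc_names, ]
    if (nrow(sub) != length(anc_names)) {
      warn(sprintf("Residue %s %s%d lacks anchor atoms; skipped.",
                   tp, resis$chain[i], resis$resno[i]))
      next
    }
    fc <- if (!is.null(formal_charges) && tp %in% names(formal_charges)) {
      formal_charges[[tp]]
    } else defaults[tp] %||% 0L
    if (is.na(fc)) fc <- 0L
    rows[[length(rows) + 1L]] <- residue_site(
      type = tp,
      anchors = tibble(atom = sub$atom, x = sub$x, y = sub$y, z = sub$z),
      site_id = sprintf("%s%s%d", substr(tp, 1, 1),
                        tolower(substr(tp, 2, nchar(tp))), resis$resno[i]),
      chain = resis$chain[i], resno = resis$resno[i], formal_charge = fc)
  }
  if (!length(rows)) abort("No usable residue sites found.")
  dplyr::bind_rows(rows)
}
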