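## Rigid-body superposition and side-chain flexibility statistics.

#' Construct a coordinate set
#'
#' A light container for labeled 3-D points with optional chain/residue
#' metadata, used for docking small reactant models and for placing
#' rotamers. Coordinates are in angstrom.
#'
#' @param df data frame with columns `atom`, `x`, `y`, `z`; optional
#'   `chain`, `resno`, `resid`, `element`, `insert`, `occupancy`. Labels
#'   must be unique unless residue metadata disambiguates them, in which
#'   case the combination must be unique.
#' @return a tibble of class `coord_set`.
#' @export
coord_set <- function(df) {
  df <- as_tibble(df)
  req <- c("atom", "x", "y", "z")
  if (!all(req %in% names(df))) {
    abort("`df` must have columns atom, x, y, z.")
  }
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    abort("Coordinates must be finite.")
  }
  keycols <- intersect(c("chain", "resno", "insert", "atom"), names(df))
  key <- do.call(paste, c(df[keycols], sep = "|"))
  if (anyDuplicated(key)) abort("Coordinate labels must be unique.")
  structure(df, class = c("coord_set", class(tibble())))
}

coord_xyz <- function(cs) unname(as.matrix(as_tibble(cs)[, c("x", "y", "z")]))

## Smallest singular value of the centered coordinates; ~0 means the
## points are (nearly) collinear and the rotation is under-determined.
geometry_rank_ok <- function(xyz, tol = 1e-6) {
  s <- svd(scale(xyz, scale = FALSE))$d
  length(s) >= 2 && s[2] > tol * max(s[1], 1)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' mapped atom pairs, the placement idiom used both for docking reactant
#' models onto crystal ligands and for placing rotamer side chains.
#' Reflections are never returned.
#'
#' @param mobile,reference [coord_set()] objects (or data frames with
#'   `atom`, `x`, `y`, `z`).
#' @param mapping data frame with columns `mobile` and `reference` giving
#'   paired atom labels, or `NULL` to match shared labels.
#' @return an object of class `superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (length 3), `rmsd` (angstrom, over mapped pairs
#'   after the transform), `n` and `transformed` (the mobile coord_set
#'   after the transform). Apply as `x_new = rotation %*% x + translation`.
#' @export
superpose <- function(mobile, reference, mapping = NULL) {
  mobile <- if (inherits(mobile, "coord_set")) mobile else coord_set(mobile)
  reference <- if (inherits(reference, "coord_set")) reference else coord_set(reference)
  if (is.null(mapping)) {
    shared <- intersect(mobile$atom, reference$atom)
    mapping <- data.frame(mobile = shared, reference = shared)
  }
  mi <- match(mapping$mobile, mobile$atom)
  ri <- match(mapping$reference, reference$atom)
  if (anyNA(mi) || anyNA(ri)) abort("Mapping names atoms absent from the coordinate sets.")
  if (length(mi) < 3) abort("Superposition needs at least three mapped pairs.")
  A <- coord_xyz(mobile)[mi, , drop = FALSE]
  B <- coord_xyz(reference)[ri, , drop = FALSE]
  if (!geometry_rank_ok(A) || !geometry_rank_ok(B)) {
    abort("Degenerate (collinear) anchor geometry: rotation is under-determined.")
  }
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2L, ca), sweep(B, 2L, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cb - as.numeric(R %*% ca)
  moved <- sweep(coord_xyz(mobile) %*% t(R), 2L, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((sweep(A %*% t(R), 2L, t_vec, "+") - B)^2)))
  transformed <- as_tibble(mobile)
  transformed$x <- moved[, 1]; transformed$y <- moved[, 2]; transformed$z <- moved[, 3]
  structure(
    list(rotation = R, translation = t_vec, rmsd = rmsd, n = length(mi),
         transformed = coord_set(transformed)),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d mapped pairs, rmsd %.4f angstrom\n", x$n, x$rmsd))
  invisible(x)
}

## ---- Side-chain flexibility -------------------------------------------

## Terminal carbon representing the charged group, per residue type.
CT_ATOM <- c(ARG = "CZ", LYS = "CE", ASP = "CG", GLU = "CD")

#' Flexibility of conserved side chains across an ensemble
#'
#' For each selected residue of an already-superposed structural ensemble,
#' computes the RMSD of the C-alpha atom and of the side-chain terminal
#' carbon Ct (Arg CZ, Lys CE, Asp CG, Glu CD) about their ensemble mean
#' positions. A Ct/C-alpha ratio well above 1 flags side chains that are
#' mobile on an otherwise rigid backbone.
#'
#' @param ensemble list of two or more superposed [coord_set()] objects
#'   with `chain`, `resno`, `resid` metadata.
#' @param selection optional data frame with columns `chain` and `resno`
#'   restricting the residues analysed; default: all residues of the first
#'   structure with a known Ct atom type.
#' @return tibble with columns `chain`, `resno`, `resid`, `rmsd_ca`,
#'   `rmsd_ct`, `ratio`, `n_structures`. Residues missing an atom in any
#'   structure are skipped with a warning.
#' @export
flexibility_stats <- function(ensemble, selection = NULL) {
  if (!is.list(ensemble) || length(ensemble) < 2) {
    abort("`ensemble` must be a list of at least two superposed structures.")
  }
  ensemble <- lapply(ensemble, function(e) if (inherits(e, "coord_set")) e else coord_set(e))
  first <- as_tibble(ensemble[[1]])
  if (is.null(selection)) {
    selection <- dplyr::distinct(
      dplyr::filter(first, toupper(.data$resid) %in% names(CT_ATOM)),
      .data$chain, .data$resno, .data$resid
    )
  } else {
    selection <- as_tibble(selection)
    if (!"resid" %in% names(selection)) {
      selection <- dplyr::left_join(
        selection,
        dplyr::distinct(first, .data$chain, .data$resno, .data$resid),
        by = c("chain", "resno"))
    }
  }
  grab <- function(cs, chain, resno, atom) {
    tab <- as_tibble(cs)
    row <- tab[tab$chain == chain & tab$resno == resno & tab$atom == atom, ]
    if (nrow(row) != 1) return(NULL)
    c(row$x, row$y, row$z)
  }
  ensemble_rmsd <- function(mat) {
    mu <- colMeans(mat)
    sqrt(mean(rowSums(sweep(mat, 2L, mu)^2)))
  }
  out <- list()
  for (i in seq_len(nrow(selection))) {
    chain <- selection$chain[i]; resno <- selection$resno[i]
    resid <- toupper(selection$resid[i])
    ct_atom <- CT_ATOM[[resid]]
    if (is.null(ct_atom)) {
      warn(sprintf("Residue %s %s%s has no defined Ct atom type; skipped.",
                   resid, chain, resno))
      next
    }
    ca <- lapply(ensemble, grab, chain = chain, resno = resno, atom = "CA")
    ct <- lapply(ensemble, grab, chain = chain, resno = resno, atom = ct_atom)
    if (any(vapply(ca, is.null, TRUE)) || any(vapply(ct, is.null, TRUE))) {
      warn(sprintf("Residue %s %s%s lacks CA or %s in some structures; skipped.",
                   resid, chain, resno, ct_atom))
      next
    }
    rmsd_ca <- ensemble_rmsd(do.call(rbind, ca))
    rmsd_ct <- ensemble_rmsd(do.call(rbind, ct))
    out[[length(out) + 1L]] <- tibble(
      chain = chain, resno = resno, resid = resid,
      rmsd_ca = rmsd_ca, rmsd_ct = rmsd_ct,
      ratio = rmsd_ct / rmsd_ca, n_structures = length(ensemble))
  }
  if (!length(out)) return(tibble(chain = character(), resno = integer(),
                                  resid = character(), rmsd_ca = numeric(),
                                  rmsd_ct = numeric(), ratio = numeric(),
                                  n_structures = integer()))
  dplyr::bind_rows(out)
}
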