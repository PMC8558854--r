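## Atomic multipole containers and moment algebra.
##
## A multipole_set is a tibble with one row per expansion center: columns
## `label`, `element`, `x`, `y`, `z` (bohr) and 35 moment columns holding
## the unique components of the traced Cartesian moments of ranks 0-4 in
## atomic units (e * bohr^k): `m0`, `m1_x`..`m1_z`, `m2_xx`..`m2_zz`,
## `m3_xxx`..`m3_zzz`, `m4_xxxx`..`m4_zzzz` (lexicographic index order).
## Trace parts of the moments are kept (CAMM convention); because the
## interaction tensors are traceless, traces never contribute to energies.

#' Construct a multipole set
#'
#' A multipole set represents a molecule or fragment as a collection of
#' atom-centered Cartesian multipole expansions of ranks 0-4 (monopole
#' through hexadecapole), the unit of all energy operations in the package.
#'
#' @param atoms a data frame with columns `label`, `x`, `y`, `z` and any of
#'   the 35 moment columns (`m0`, `m1_x`, ..., `m4_zzzz`); missing moment
#'   columns are filled with zero. An optional `element` column carries the
#'   chemical element symbol.
#' @param fragment_id string identifying the fragment (e.g. `"RS"`, `"TS"`,
#'   `"Glu83:rot3"`).
#' @param formal_charge integer formal charge in e, or `NULL` if undeclared.
#'   When declared, the monopoles must sum to it within `1e-6` e.
#' @param units units of the input coordinates: `"bohr"` (default) or
#'   `"angstrom"`. Coordinates are stored in bohr.
#' @return a tibble of subclass `multipole_set` with attributes
#'   `fragment_id` and `formal_charge`.
#' @examples
#' multipole_set(
#'   tibble::tibble(label = "Q1", x = 0, y = 0, z = 0, m0 = 1),
#'   fragment_id = "probe", formal_charge = 1
#' )
#' @export
multipole_set <- function(atoms, fragment_id = "fragment", formal_charge = NULL,
                          units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  atoms <- as_tibble(atoms)
  req <- c("label", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    abort(paste0("`atoms` must have columns ", paste(req, collapse = ", "), "."))
  }
  if (!"element" %in% names(atoms)) atoms$element <- NA_character_
  mcols <- moment_col_names_all()
  for (col in mcols) if (!col %in% names(atoms)) atoms[[col]] <- 0
  atoms <- atoms[, c("label", "element", "x", "y", "z", mcols)]
  atoms$label <- as.character(atoms$label)
  if (anyDuplicated(atoms$label)) {
    abort("Atom labels must be unique within a multipole set.")
  }
  if (units == "angstrom") {
    atoms[c("x", "y", "z")] <- atoms[c("x", "y", "z")] * BOHR_PER_ANGSTROM
  }
  if (!is.null(formal_charge)) {
    if (abs(sum(atoms$m0) - formal_charge) > 1e-6) {
      abort(sprintf(
        "Monopoles sum to %.8f e but formal_charge is %g e (tolerance 1e-6).",
        sum(atoms$m0), formal_charge))
    }
  }
  new_multipole_set(atoms, fragment_id, formal_charge)
}

new_multipole_set <- function(atoms, fragment_id, formal_charge) {
  structure(
    atoms,
    fragment_id = fragment_id,
    formal_charge = formal_charge,
    class = c("multipole_set", class(tibble()))
  )
}

#' @export
print.multipole_set <- function(x, ...) {
  cat("<multipole_set> fragment", encodeString(attr(x, "fragment_id"), quote = '"'),
      "-", nrow(x), "expansion centers (coordinates in bohr)\n")
  if (!is.null(attr(x, "formal_charge"))) {
    cat("  formal charge:", attr(x, "formal_charge"), "e\n")
  }
  NextMethod()
}

fragment_id <- function(m) attr(m, "fragment_id") %||% "fragment"

center_matrix <- function(m) unname(as.matrix(m[, c("x", "y", "z")]))

moment_matrix <- function(m) unname(as.matrix(m[, moment_col_names_all()]))

assert_multipole_set <- function(m, arg = "m") {
  if (!inherits(m, "multipole_set")) {
    abort(sprintf("`%s` must be a multipole_set.", arg))
  }
  invisible(m)
}

## ---- Exact moments of point charges -----------------------------------

#' Exact atomic multipole moments of assigned point charges
#'
#' Computes, for each expansion center, the exact traced Cartesian moments
#' of ranks 0-4 of the point charges assigned to it. Because the moments
#' are exact, energies and potentials computed from the result converge to
#' the direct Coulomb sum as the truncation order and separation grow;
#' synthetic fixtures rely on this as their ground truth.
#'
#' @param charges data frame with columns `q` (charge, e) and `x`, `y`, `z`
#'   (positions, bohr).
#' @param centers matrix or data frame of expansion-center coordinates
#'   (bohr), one row per center.
#' @param assignment integer vector mapping each charge to a center row;
#'   every charge must be assigned.
#' @param fragment_id,labels passed to the resulting [multipole_set()];
#'   `labels` defaults to `Q1`, `Q2`, ...
#' @return a [multipole_set()] with one row per center.
#' @examples
#' ch <- tibble::tibble(q = 1, x = 0, y = 0, z = 0.5)
#' atomic_moments_from_point_charges(ch, matrix(0, 1, 3), 1L)
#' @export
atomic_moments_from_point_charges <- function(charges, centers, assignment,
                                              fragment_id = "cluster",
                                              labels = NULL) {
  charges <- as_tibble(charges)
  centers <- unname(as.matrix(as.data.frame(centers)))
  if (ncol(centers) != 3) abort("`centers` must have three columns.")
  nq <- nrow(charges)
  assignment <- as.integer(assignment)
  if (length(assignment) != nq || anyNA(assignment) ||
      any(assignment < 1L | assignment > nrow(centers))) {
    abort("Every charge must be assigned to exactly one center.")
  }
  nc <- nrow(centers)
  if (is.null(labels)) labels <- paste0("Q", seq_len(nc))
  mom <- matrix(0, nrow = nc, ncol = length(moment_col_names_all()))
  colnames(mom) <- moment_col_names_all()
  for (ci in seq_len(nc)) {
    sel <- assignment == ci
    if (!any(sel)) next
    q <- charges$q[sel]
    d <- cbind(charges$x[sel], charges$y[sel], charges$z[sel]) -
      matrix(centers[ci, ], nrow = sum(sel), ncol = 3, byrow = TRUE)
    col <- 1L
    for (k in MOMENT_RANKS) {
      tuples <- moment_tuples(k)
      for (iu in seq_len(nrow(tuples))) {
        v <- q
        for (pos in seq_len(k)) v <- v * d[, tuples[iu, pos]]
        mom[ci, col] <- sum(v)
        col <- col + 1L
      }
    }
  }
  atoms <- as_tibble(as.data.frame(mom))
  atoms$label <- labels
  atoms$x <- centers[, 1]; atoms$y <- centers[, 2]; atoms$z <- centers[, 3]
  fc <- sum(charges$q)
  fc <- if (abs(fc - round(fc)) < 1e-9) as.integer(round(fc)) else NULL
  multipole_set(atoms, fragment_id = fragment_id, formal_charge = fc)
}

## ---- Translation ------------------------------------------------------

## Table for shifting an expansion center: the rank-k moment about the new
## center is a binomial sum over lower-rank moments times powers of
## s = old_center - new_center. Rows: target global component `ig`, source
## global component `im`, s-exponents and subset count.
translation_table <- function() {
  if (!is.null(.catfield_cache$trans_table)) return(.catfield_cache$trans_table)
  rows <- list()
  for (k in MOMENT_RANKS) {
    tuples <- moment_tuples(k)
    for (iu in seq_len(nrow(tuples))) {
      tuple <- tuples[iu, ]
      ig <- rank_offset(k) + iu
      nsub <- if (k == 0) list(integer()) else {
        unlist(lapply(0:k, function(j) utils::combn(k, j, simplify = FALSE)),
               recursive = FALSE)
      }
      acc <- list()
      for (S in nsub) {
        sub <- sort(tuple[S])
        j <- length(sub)
        tj <- moment_tuples(j)
        imj <- if (j == 0) 1L else {
          rank_offset(j) + match(paste(sub, collapse = ""),
                                 apply(tj, 1L, paste, collapse = ""))
        }
        rest <- tuple[setdiff(seq_len(k), S)]
        ex <- tabulate(rest, nbins = 3L)
        key <- paste(imj, ex[1], ex[2], ex[3], sep = "_")
        prev <- acc[[key]]
        acc[[key]] <- if (is.null(prev)) c(ig, imj, ex, 1) else prev + c(0, 0, 0, 0, 0, 1)
      }
      rows <- c(rows, acc)
    }
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("ig", "im", "ex", "ey", "ez", "cnt")
  .catfield_cache$trans_table <- tab
  tab
}

translate_moment_vector <- function(mom, s) {
  tab <- translation_table()
  out <- numeric(length(mom))
  pw <- function(b, e) if (e == 0) 1 else b^e
  for (r in seq_len(nrow(tab))) {
    v <- tab[r, "cnt"] * mom[tab[r, "im"]] *
      pw(s[1], tab[r, "ex"]) * pw(s[2], tab[r, "ey"]) * pw(s[3], tab[r, "ez"])
    out[tab[r, "ig"]] <- out[tab[r, "ig"]] + v
  }
  out
}

#' Translate a multipole expansion to a new center
#'
#' Re-expands atomic moments about `new_center`, preserving the far-field
#' potential (up to the common rank-4 truncation). When the set has several
#' atoms their translated expansions are summed, so this doubles as the
#' molecular-moment collector behind [total_molecular_moments()].
#' Translation by a zero vector is the identity; the monopole never changes.
#'
#' @param m a [multipole_set()].
#' @param new_center numeric length-3, the new expansion center (bohr).
#' @param label label for the resulting single center.
#' @return a one-row [multipole_set()] centered at `new_center`.
#' @export
translate_moments <- function(m, new_center, label = "center") {
  assert_multipole_set(m)
  new_center <- as.numeric(new_center)
  if (length(new_center) != 3) abort("`new_center` must be length 3.")
  centers <- center_matrix(m)
  mom <- moment_matrix(m)
  total <- numeric(ncol(mom))
  for (i in seq_len(nrow(m))) {
    s <- centers[i, ] - new_center
    total <- total + if (sum(s^2) == 0) mom[i, ] else translate_moment_vector(mom[i, ], s)
  }
  atoms <- as_tibble(as.data.frame(matrix(total, nrow = 1,
                                          dimnames = list(NULL, moment_col_names_all()))))
  atoms$label <- label
  atoms$element <- NA_character_
  atoms$x <- new_center[1]; atoms$y <- new_center[2]; atoms$z <- new_center[3]
  new_multipole_set(
    atoms[, c("label", "element", "x", "y", "z", moment_col_names_all())],
    fragment_id = fragment_id(m), formal_charge = attr(m, "formal_charge")
  )
}

#' Total molecular multipole moments about an origin
#'
#' Sums all atomic expansions translated to a common origin. The result is
#' invariant under any re-partitioning of the same underlying point charges
#' among centers, which makes it the natural diagnostic for moment
#' bookkeeping; the total monopole equals the formal charge.
#'
#' @param m a [multipole_set()].
#' @param origin numeric length-3 origin (bohr), default the coordinate origin.
#' @return a named list of tensors `rank0` (scalar) through `rank4`
#'   (full symmetric arrays), with the unique-component vector in
#'   attribute `"unique"`.
#' @export
total_molecular_moments <- function(m, origin = c(0, 0, 0)) {
  one <- translate_moments(m, origin)
  mom <- drop(moment_matrix(one))
  out <- lapply(MOMENT_RANKS, function(k) {
    idx <- rank_offset(k) + seq_len(n_unique(k))
    unique_to_full(mom[idx], k)
  })
  names(out) <- paste0("rank", MOMENT_RANKS)
  attr(out, "unique") <- setNames(mom, moment_col_names_all())
  out
}

## ---- Rotation ---------------------------------------------------------

rotate_full_tensor <- function(arr, k, R) {
  if (k == 0) return(arr)
  if (k == 1) return(as.numeric(R %*% arr))
  d <- rep(3L, k)
  a <- array(arr, d)
  for (i in seq_len(k)) {
    a <- array(R %*% matrix(a, nrow = 3), d)
    a <- aperm(a, c(2:k, 1))
  }
  a
}

assert_rotation <- function(rotation, tol = 1e-8) {
  rotation <- unname(as.matrix(rotation))
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > tol ||
      abs(det(rotation) - 1) > tol) {
    abort("`rotation` must be a 3x3 proper orthonormal matrix (det +1).",
          class = "catfield_invalid_rotation")
  }
  rotation
}

#' Rotate a multipole set (centers and moment tensors)
#'
#' Applies a proper rotation about the coordinate origin: each center is
#' rotated and every rank-k moment tensor is rotated by applying the matrix
#' to each of its k indices. Interaction energies are invariant under a
#' common rotation of all sets involved.
#'
#' @param m a [multipole_set()].
#' @param rotation 3x3 orthonormal matrix with determinant +1
#'   (tolerance 1e-8).
#' @return the rotated [multipole_set()].
#' @export
rotate_moments <- function(m, rotation) {
  transform_multipole_set(m, rotation = rotation)
}

## Rigid motion x -> R x + t (t in bohr); the workhorse behind
## rotate_moments() and place_rotamer().
transform_multipole_set <- function(m, rotation = diag(3), translation = c(0, 0, 0)) {
  assert_multipole_set(m)
  rotation <- assert_rotation(rotation)
  translation <- as.numeric(translation)
  centers <- center_matrix(m) %*% t(rotation)
  centers <- sweep(centers, 2L, translation, "+")
  mom <- moment_matrix(m)
  for (i in seq_len(nrow(m))) {
    for (k in MOMENT_RANKS[-1]) {
      idx <- rank_offset(k) + seq_len(n_unique(k))
      arr <- unique_to_full(mom[i, idx], k)
      mom[i, idx] <- full_to_unique(rotate_full_tensor(arr, k, rotation), k)
    }
  }
  atoms <- as_tibble(as.data.frame(mom))
  names(atoms) <- moment_col_names_all()
  atoms$label <- m$label
  atoms$element <- m$element
  atoms$x <- centers[, 1]; atoms$y <- centers[, 2]; atoms$z <- centers[, 3]
  new_multipole_set(atoms[, c("label", "element", "x", "y", "z", moment_col_names_all())],
                    fragment_id = fragment_id(m),
                    formal_charge = attr(m, "formal_charge"))
}

#' Combine multipole sets into one fragment
#'
#' @param ... multipole_set objects sharing a frame.
#' @param fragment_id id for the combined set.
#' @return a [multipole_set()]; labels are prefixed with their source
#'   fragment id when needed to stay unique.
#' @export
bind_multipole_sets <- function(..., fragment_id = "combined") {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "multipole_set")) {
    sets <- sets[[1]]
  }
  for (s in sets) assert_multipole_set(s)
  tabs <- lapply(sets, function(s) as_tibble(as.data.frame(s)))
  labels <- unlist(lapply(tabs, function(t) t$label))
  if (anyDuplicated(labels)) {
    tabs <- lapply(seq_along(tabs), function(i) {
      tabs[[i]]$label <- paste0(fragment_id(sets[[i]]), ":", tabs[[i]]$label)
      tabs[[i]]
    })
  }
  out <- dplyr::bind_rows(tabs)
  fc <- vapply(sets, function(s) attr(s, "formal_charge") %||% NA_integer_, 1L)
  new_multipole_set(out, fragment_id,
                    formal_charge = if (anyNA(fc)) NULL else sum(fc))
}
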