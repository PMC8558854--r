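## Differential transition-state stabilization (DTSS) and static
## catalytic-field grids.
##
## DTSS of an environment fragment C is E_el(TS, C) - E_el(RS, C): the
## barrier change caused by the fragment's electrostatic interaction with
## the reacting system, negative when the fragment stabilizes the
## transition state more than the substrate. The static catalytic field
## Delta_S maps the same quantity for a probe unit charge: it is defined
## here as Delta_S = -(V_TS - V_RS), so a +1 e charge placed at a node
## changes the barrier by -Delta_S, and positive Delta_S marks regions
## where a positive charge is catalytic.

#' Bundle substrate and transition-state multipole sets
#'
#' @param rs,ts [multipole_set()] objects for the substrate (reactant
#'   state) and transition state, docked in a common frame.
#' @param e_rs,e_ts optional bare electronic energies (hartree) of the
#'   isolated models; when both are given the bare barrier
#'   `B0 = (e_ts - e_rs)` (converted to kcal/mol) is available.
#' @return an object of class `species_pair`.
#' @export
species_pair <- function(rs, ts, e_rs = NULL, e_ts = NULL) {
  assert_multipole_set(rs, "rs"); assert_multipole_set(ts, "ts")
  structure(list(rs = rs, ts = ts, e_rs = e_rs, e_ts = e_ts),
            class = "species_pair")
}

#' @export
print.species_pair <- function(x, ...) {
  cat("<species_pair> RS:", nrow(x$rs), "centers; TS:", nrow(x$ts), "centers\n")
  b0 <- bare_barrier(x)
  if (!is.null(b0)) cat("  bare barrier B0:", sprintf("%.4f", b0), "kcal/mol\n")
  invisible(x)
}

#' Bare activation barrier of a species pair
#'
#' @param pair a [species_pair()] carrying both bare energies.
#' @return `(e_ts - e_rs)` in kcal/mol, or `NULL` when an energy is absent.
#' @export
bare_barrier <- function(pair) {
  if (is.null(pair$e_rs) || is.null(pair$e_ts)) return(NULL)
  (pair$e_ts - pair$e_rs) * HARTREE_TO_KCAL
}

assert_species_pair <- function(pair) {
  if (!inherits(pair, "species_pair")) abort("`pair` must be a species_pair.")
  invisible(pair)
}

#' Differential transition-state stabilization of an environment fragment
#'
#' Computes `E_el(TS, env) - E_el(RS, env)` with the CAMM expansion of
#' [pair_energy()]. Negative values lower the activation barrier. Because
#' the electrostatic term is additive, the DTSS of a union of disjoint
#' fragments equals the sum of their individual DTSS values.
#'
#' @param env a [multipole_set()] for the environment fragment, in the
#'   pair's frame.
#' @param pair a [species_pair()].
#' @param max_order truncation rank passed to [pair_energy()].
#' @return DTSS in kcal/mol.
#' @export
dtss <- function(env, pair, max_order = 4) {
  assert_multipole_set(env, "env")
  assert_species_pair(pair)
  e_ts <- pair_energy(pair$ts, env, max_order = max_order)
  e_rs <- pair_energy(pair$rs, env, max_order = max_order)
  (e_ts - e_rs) * HARTREE_TO_KCAL
}

#' Point-charge environment
#'
#' The extreme approximation of the environment: bare point charges such as
#' side-chain formal charges.
#'
#' @param q charges (e).
#' @param pos n x 3 matrix or data frame of positions.
#' @param label optional labels (unique), default `"q1"`, `"q2"`, ...
#' @param units units of `pos`: `"angstrom"` (default, as in structure
#'   files) or `"bohr"`.
#' @return a tibble of class `point_charges` with bohr coordinates.
#' @export
point_charges <- function(q, pos, label = NULL, units = c("angstrom", "bohr")) {
  units <- match.arg(units)
  pos <- unname(as.matrix(as.data.frame(pos)))
  if (length(q) == 0) {
    out <- tibble(q = numeric(), x = numeric(), y = numeric(), z = numeric(),
                  label = character())
    return(structure(out, class = c("point_charges", class(tibble()))))
  }
  if (ncol(pos) != 3 || nrow(pos) != length(q)) {
    abort("`pos` must be an n x 3 matrix matching `q`.")
  }
  if (any(!is.finite(q)) || any(!is.finite(pos))) abort("Charges and positions must be finite.")
  if (units == "angstrom") pos <- pos * BOHR_PER_ANGSTROM
  if (is.null(label)) label <- paste0("q", seq_along(q))
  if (anyDuplicated(label)) abort("Point-charge labels must be unique.")
  out <- tibble(q = as.numeric(q), x = pos[, 1], y = pos[, 2], z = pos[, 3],
                label = as.character(label))
  structure(out, class = c("point_charges", class(tibble())))
}

#' DTSS of a point-charge environment
#'
#' The point-charge extreme of the DTSS expression:
#' `sum_i q_i (V_TS(r_i) - V_RS(r_i))`. Exactly equal to [dtss()] with a
#' monopole-only environment.
#'
#' @param env a [point_charges()] object (or a data frame with columns
#'   `q`, `x`, `y`, `z` in bohr).
#' @param pair a [species_pair()].
#' @param max_order truncation rank for the reacting-system potentials.
#' @return DTSS in kcal/mol; `0` for an empty environment.
#' @export
dtss_point_charge <- function(env, pair, max_order = 4) {
  assert_species_pair(pair)
  env <- as_tibble(env)
  if (nrow(env) == 0) return(0)
  pts <- unname(as.matrix(env[, c("x", "y", "z")]))
  dv <- potential(pair$ts, pts, max_order = max_order) -
    potential(pair$rs, pts, max_order = max_order)
  sum(env$q * dv) * HARTREE_TO_KCAL
}

## ---- Static catalytic field -------------------------------------------

#' Static catalytic field on a regular grid
#'
#' Maps `Delta_S = -(V_TS - V_RS)` (kcal/(mol e)) on a regular 3-D grid:
#' the barrier change caused by a unit +1 e point charge at node i is
#' `-Delta_S(i)`, so positive `Delta_S` marks regions where a positive
#' charge is catalytic and negative `Delta_S` regions favouring negative
#' charges. Nodes within 0.5 angstrom of any expansion center are masked
#' (`NA`, column `masked`): the near-field expansion is not meaningful
#' there and values are never fabricated.
#'
#' @param pair a [species_pair()].
#' @param origin numeric length-3 grid origin (angstrom); default places
#'   the grid `padding` angstrom below the bounding box of the RS and TS
#'   atoms.
#' @param spacing grid spacing (angstrom), default 0.5.
#' @param shape integer length-3 node counts; default spans the padded
#'   bounding box.
#' @param padding padding (angstrom) around the atoms for the default grid.
#' @param max_order truncation rank for the potentials.
#' @return a tibble of class `field_grid` with columns `x`, `y`, `z`
#'   (angstrom), `delta_s` (kcal/(mol e); `NA` where masked) and `masked`;
#'   attributes `origin`, `spacing`, `shape`.
#' @export
static_field <- function(pair, origin = NULL, spacing = 0.5, shape = NULL,
                         padding = 4, max_order = 4) {
  assert_species_pair(pair)
  if (!is.null(spacing) && (length(spacing) != 1 || spacing <= 0)) {
    abort("`spacing` must be a single positive number (angstrom).")
  }
  atoms_ang <- rbind(center_matrix(pair$rs), center_matrix(pair$ts)) * ANGSTROM_PER_BOHR
  if (is.null(origin)) origin <- apply(atoms_ang, 2L, min) - padding
  origin <- as.numeric(origin)
  if (is.null(shape)) {
    upper <- apply(atoms_ang, 2L, max) + padding
    shape <- pmax(2L, as.integer(floor((upper - origin) / spacing)) + 1L)
  }
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1) || prod(shape) == 0) {
    abort("Empty grid: `shape` must give at least one node per axis.")
  }
  ## z fastest, then y, then x (cube-file ordering)
  nodes <- expand.grid(
    iz = seq_len(shape[3]) - 1L,
    iy = seq_len(shape[2]) - 1L,
    ix = seq_len(shape[1]) - 1L
  )[, c("ix", "iy", "iz")]
  pts_ang <- cbind(origin[1] + nodes$ix * spacing,
                   origin[2] + nodes$iy * spacing,
                   origin[3] + nodes$iz * spacing)
  d2 <- matrix(Inf, nrow = nrow(pts_ang), ncol = 1)
  for (i in seq_len(nrow(atoms_ang))) {
    di <- rowSums(sweep(pts_ang, 2L, atoms_ang[i, ], "-")^2)
    d2 <- pmin(d2, di)
  }
  masked <- as.vector(sqrt(d2) < GRID_MASK_ANGSTROM)
  delta_s <- rep(NA_real_, nrow(pts_ang))
  if (any(!masked)) {
    pts_bohr <- pts_ang[!masked, , drop = FALSE] * BOHR_PER_ANGSTROM
    dv <- potential(pair$ts, pts_bohr, max_order = max_order) -
      potential(pair$rs, pts_bohr, max_order = max_order)
    delta_s[!masked] <- -dv * HARTREE_TO_KCAL
  }
  out <- tibble(x = pts_ang[, 1], y = pts_ang[, 2], z = pts_ang[, 3],
                delta_s = delta_s, masked = masked)
  new_field_grid(out, origin = origin, spacing = spacing, shape = shape)
}

new_field_grid <- function(df, origin, spacing, shape) {
  structure(as_tibble(df),
            origin = as.numeric(origin), spacing = as.numeric(spacing),
            shape = as.integer(shape),
            class = c("field_grid", class(tibble())))
}

#' @export
print.field_grid <- function(x, ...) {
  sh <- attr(x, "shape")
  cat("<field_grid>", paste(sh, collapse = " x "), "nodes, spacing",
      attr(x, "spacing"), "angstrom;", sum(x$masked), "masked\n")
  NextMethod()
}

#' Per-residue barrier estimate
#'
#' Combines a bare activation barrier `B0` of the isolated reacting system
#' with additive per-residue DTSS contributions into the crude activation
#' energy estimate `B0 + sum(DTSS)`. Only the topology of the contributing
#' residues enters; the estimate ranks catalytic residues rather than
#' predicting absolute barriers.
#'
#' @param b0 bare barrier (kcal/mol), or a [species_pair()] whose bare
#'   energies supply it.
#' @param contributions named numeric vector, or data frame with columns
#'   `residue` and `dtss` (optionally `dtss_crystal`), of per-residue DTSS
#'   values (kcal/mol). May be empty.
#' @return an object of class `barrier_estimate` with fields `b0`,
#'   `contributions` (tibble), `sum_dtss` and `total`.
#' @examples
#' barrier_estimate(18.95, c(Glu83 = -10.27, Arg259 = 7.03))
#' @export
barrier_estimate <- function(b0, contributions = numeric()) {
  if (inherits(b0, "species_pair")) {
    b0 <- bare_barrier(b0)
    if (is.null(b0)) abort("The species_pair does not carry both bare energies.")
  }
  if (length(b0) != 1 || !is.finite(b0)) abort("`b0` must be a finite scalar (kcal/mol).")
  if (is.data.frame(contributions)) {
    ctab <- as_tibble(contributions)
    if (!all(c("residue", "dtss") %in% names(ctab))) {
      abort("`contributions` data frame needs columns `residue` and `dtss`.")
    }
  } else {
    contributions <- unlist(contributions)
    ctab <- tibble(residue = names(contributions) %||% character(),
                   dtss = as.numeric(contributions))
    if (nrow(ctab) > 0 && any(!nzchar(ctab$residue))) {
      ctab$residue <- paste0("res", seq_len(nrow(ctab)))
    }
  }
  if (nrow(ctab) > 0 && any(!is.finite(ctab$dtss))) abort("DTSS contributions must be finite.")
  sum_dtss <- sum(ctab$dtss)
  structure(
    list(b0 = b0, contributions = ctab, sum_dtss = sum_dtss,
         total = b0 + sum_dtss),
    class = "barrier_estimate"
  )
}

#' @export
print.barrier_estimate <- function(x, ...) {
  cat("<barrier_estimate> (kcal/mol)\n")
  if (nrow(x$contributions) > 0) {
    for (i in seq_len(nrow(x$contributions))) {
      cat(sprintf("  %-10s %+8.2f\n", x$contributions$residue[i], x$contributions$dtss[i]))
    }
  }
  cat(sprintf("  %-10s %+8.2f\n", "sum DTSS", x$sum_dtss))
  cat(sprintf("  %-10s %+8.2f\n", "B0", x$b0))
  cat(sprintf("  %-10s %+8.2f\n", "B0+sum", x$total))
  invisible(x)
}
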