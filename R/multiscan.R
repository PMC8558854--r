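## MULTISCAN: combinatorial search over side-chain rotamer combinations.
##
## The objective minimized is
##   J(a) = sum_i DTSS(site_i, rotamer a_i) +
##          sum_{i<j} E_el(rotamer a_i, rotamer a_j)
## (kcal/mol, electrostatics in the common docked frame). The pairwise
## term is what distinguishes MULTISCAN from independent per-residue
## optimization: strongly interacting charged side chains (salt bridges)
## can trade individual DTSS for a better joint arrangement.

## Precompute per-site placements, DTSS values and pairwise energy tables.
scan_tables <- function(sites, library, pair, max_order = 4,
                        clash_filter = FALSE, clash_dist = 2.0) {
  sites <- as_tibble(sites)
  if (nrow(sites) == 0) abort("No sites given.")
  placements <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sub <- library_rotamers(library, sites$type[i])  # errors name the type
    placements[[i]] <- lapply(sub$rotamer_id, function(rid) {
      place_rotamer(sites[i, ], rid, library)
    })
    names(placements[[i]]) <- sub$rotamer_id
  }
  k <- lengths(placements)
  dtss_tab <- lapply(seq_along(placements), function(i) {
    vapply(placements[[i]], dtss, 0, pair = pair, max_order = max_order)
  })
  pair_tab <- list()
  n <- length(placements)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        mat <- matrix(0, k[i], k[j])
        for (ri in seq_len(k[i])) for (rj in seq_len(k[j])) {
          mat[ri, rj] <- pair_energy(placements[[i]][[ri]], placements[[j]][[rj]],
                                     max_order = max_order) * HARTREE_TO_KCAL
        }
        pair_tab[[paste(i, j)]] <- mat
      }
    }
  }
  feasible <- lapply(seq_along(placements), function(i) rep(TRUE, k[i]))
  pair_feasible <- NULL
  if (clash_filter) {
    target <- heavy_xyz_ang(bind_multipole_sets(pair$rs, pair$ts, fragment_id = "RSTS"))
    for (i in seq_along(placements)) {
      for (ri in seq_len(k[i])) {
        xyz <- heavy_xyz_ang(placements[[i]][[ri]])
        if (min_cross_distance(xyz, target) < clash_dist) feasible[[i]][ri] <- FALSE
      }
    }
    pair_feasible <- list()
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        ok <- matrix(TRUE, k[i], k[j])
        for (ri in seq_len(k[i])) for (rj in seq_len(k[j])) {
          ok[ri, rj] <- min_cross_distance(heavy_xyz_ang(placements[[i]][[ri]]),
                                           heavy_xyz_ang(placements[[j]][[rj]])) >= clash_dist
        }
        pair_feasible[[paste(i, j)]] <- ok
      }
    }
  }
  list(sites = sites, placements = placements, k = k,
       rotamer_ids = lapply(placements, names),
       dtss = dtss_tab, pair = pair_tab,
       feasible = feasible, pair_feasible = pair_feasible,
       max_order = max_order, clash_filter = clash_filter)
}

heavy_xyz_ang <- function(m) {
  el <- toupper(ifelse(is.na(m$element), "X", m$element))
  center_matrix(m)[el != "H", , drop = FALSE] * ANGSTROM_PER_BOHR
}

min_cross_distance <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  min_interset_distance(a, b)
}

tables_objective <- function(tabs, idx) {
  n <- length(idx)
  if (any(!vapply(seq_len(n), function(i) tabs$feasible[[i]][idx[i]], TRUE))) {
    return(list(objective = Inf, dtss_total = Inf, pair_total = Inf, feasible = FALSE))
  }
  dt <- vapply(seq_len(n), function(i) tabs$dtss[[i]][idx[i]], 0)
  pt <- 0
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (!is.null(tabs$pair_feasible) &&
          !tabs$pair_feasible[[paste(i, j)]][idx[i], idx[j]]) {
        return(list(objective = Inf, dtss_total = Inf, pair_total = Inf, feasible = FALSE))
      }
      pt <- pt + tabs$pair[[paste(i, j)]][idx[i], idx[j]]
    }
  }
  list(objective = sum(dt) + pt, dtss_total = sum(dt), pair_total = pt,
       feasible = TRUE, dtss = dt)
}

#' MULTISCAN objective of a rotamer assignment
#'
#' Scores one complete assignment: the sum of per-site DTSS values plus
#' all inter-rotamer electrostatic interaction energies in the docked
#' frame. With the optional clash filter, assignments placing heavy atoms
#' closer than `clash_dist` angstrom to the reacting system or to another
#' placed rotamer are marked infeasible rather than scored.
#'
#' @param assignment named (by `site_id`) or positional vector of rotamer
#'   ids, one per site.
#' @param sites site tibble ([residue_site()] rows).
#' @param library a [rotamer_library()].
#' @param pair a [species_pair()].
#' @param max_order CAMM truncation rank.
#' @param clash_filter,clash_dist steric filter (off by default; the
#'   scoring itself is purely electrostatic).
#' @return list with `objective`, `dtss_total`, `pair_total` (kcal/mol),
#'   per-site `breakdown` tibble, `pair_energies` tibble and `feasible`.
#' @export
scan_objective <- function(assignment, sites, library, pair, max_order = 4,
                           clash_filter = FALSE, clash_dist = 2.0) {
  sites <- as_tibble(sites)
  assignment <- resolve_assignment(assignment, sites)
  tabs <- scan_tables(sites, library, pair, max_order = max_order,
                      clash_filter = clash_filter, clash_dist = clash_dist)
  idx <- assignment_index(tabs, assignment)
  sc <- tables_objective(tabs, idx)
  list(
    objective = sc$objective,
    dtss_total = sc$dtss_total,
    pair_total = sc$pair_total,
    feasible = sc$feasible,
    breakdown = tibble(site_id = sites$site_id, rotamer_id = assignment,
                       dtss = if (sc$feasible) sc$dtss else NA_real_),
    pair_energies = pair_energy_table(tabs, idx)
  )
}

resolve_assignment <- function(assignment, sites) {
  if (!is.null(names(assignment)) && all(nzchar(names(assignment)))) {
    miss <- setdiff(sites$site_id, names(assignment))
    if (length(miss)) abort(paste("Assignment misses sites:", paste(miss, collapse = ", ")))
    assignment <- assignment[sites$site_id]
  }
  if (length(assignment) != nrow(sites)) {
    abort("Assignment must name one rotamer per site.")
  }
  as.character(assignment)
}

assignment_index <- function(tabs, assignment) {
  vapply(seq_along(assignment), function(i) {
    ix <- match(assignment[i], tabs$rotamer_ids[[i]])
    if (is.na(ix)) abort(sprintf("Rotamer %s unknown for site %s.",
                                 assignment[i], tabs$sites$site_id[i]))
    ix
  }, 1L)
}

pair_energy_table <- function(tabs, idx) {
  n <- length(idx)
  if (n < 2) {
    return(tibble(site_i = character(), site_j = character(), energy = numeric()))
  }
  rows <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    rows[[length(rows) + 1L]] <- tibble(
      site_i = tabs$sites$site_id[i], site_j = tabs$sites$site_id[j],
      energy = tabs$pair[[paste(i, j)]][idx[i], idx[j]])
  }
  dplyr::bind_rows(rows)
}

#' Search rotamer combinations minimizing the MULTISCAN objective
#'
#' Exhaustive mode enumerates every assignment (up to `cap`) and returns
#' the global minimum; ties are broken lexicographically by (site order,
#' rotamer id), so the result is deterministic and independent of any
#' seed. Iterative mode runs cyclic single-site best response from the
#' crystal rotamers (when given; otherwise each site's first rotamer)
#' until a full pass changes nothing. The objective strictly decreases on
#' every accepted move, so the iteration terminates; it can stop in a
#' local minimum, never below the exhaustive optimum.
#'
#' @inheritParams scan_objective
#' @param mode `"exhaustive"` or `"iterative"`.
#' @param cap maximum number of assignments for exhaustive mode.
#' @return an object of class `multiscan_result`: per-site tibble with
#'   chosen `rotamer_id` and `dtss`, plus attributes holding the
#'   objective, the DTSS/pairwise split, the pairwise-energy table, the
#'   mode and (for iterative mode) the move trace. See [tidy.multiscan_result()].
#' @export
multiscan <- function(sites, library, pair,
                      mode = c("exhaustive", "iterative"),
                      max_order = 4, clash_filter = FALSE, clash_dist = 2.0,
                      cap = 1e6) {
  mode <- match.arg(mode)
  sites <- as_tibble(sites)
  tabs <- scan_tables(sites, library, pair, max_order = max_order,
                      clash_filter = clash_filter, clash_dist = clash_dist)
  if (mode == "exhaustive") {
    if (prod(tabs$k) > cap) {
      abort(sprintf("Exhaustive search over %g assignments exceeds cap %g.",
                    prod(tabs$k), cap))
    }
    res <- multiscan_exhaustive(tabs)
  } else {
    res <- multiscan_iterative(tabs)
  }
  sc <- tables_objective(tabs, res$idx)
  if (!is.finite(sc$objective)) abort("No feasible assignment (clash filter rejected all).")
  chosen <- vapply(seq_along(res$idx), function(i) tabs$rotamer_ids[[i]][res$idx[i]], "")
  out <- tibble(site_id = sites$site_id, chain = sites$chain, resno = sites$resno,
                type = sites$type, rotamer_id = chosen, dtss = sc$dtss)
  structure(out,
            objective = sc$objective, dtss_total = sc$dtss_total,
            pair_total = sc$pair_total,
            pair_energies = pair_energy_table(tabs, res$idx),
            mode = mode, trace = res$trace, max_order = max_order,
            class = c("multiscan_result", class(tibble())))
}

multiscan_exhaustive <- function(tabs) {
  n <- length(tabs$k)
  ## expand.grid varies the first factor fastest; feeding reversed site
  ## order and flipping back yields rows in lexicographic order with
  ## site 1 most significant, so `which.min` lands on the tie-break winner.
  A <- as.matrix(expand.grid(rev(lapply(tabs$k, seq_len))))[, n:1, drop = FALSE]
  J <- numeric(nrow(A))
  for (i in seq_len(n)) {
    d <- tabs$dtss[[i]]
    d[!tabs$feasible[[i]]] <- Inf
    J <- J + d[A[, i]]
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      P <- tabs$pair[[paste(i, j)]]
      if (!is.null(tabs$pair_feasible)) P[!tabs$pair_feasible[[paste(i, j)]]] <- Inf
      J <- J + P[cbind(A[, i], A[, j])]
    }
  }
  best <- which.min(J)
  list(idx = A[best, ], trace = NULL)
}

multiscan_iterative <- function(tabs) {
  n <- length(tabs$k)
  idx <- vapply(seq_len(n), function(i) {
    cr <- tabs$sites$crystal_rotamer[i]
    if (!is.na(cr) && cr %in% tabs$rotamer_ids[[i]]) match(cr, tabs$rotamer_ids[[i]]) else 1L
  }, 1L)
  trace <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    changed <- FALSE
    for (i in seq_len(n)) {
      cand <- vapply(seq_len(tabs$k[i]), function(r) {
        trial <- idx; trial[i] <- r
        tables_objective(tabs, trial)$objective
      }, 0)
      best <- which.min(cand)  # ties -> lowest rotamer index
      if (cand[best] < tables_objective(tabs, idx)$objective) {
        trace[[length(trace) + 1L]] <- tibble(
          pass = pass, site_id = tabs$sites$site_id[i],
          from = tabs$rotamer_ids[[i]][idx[i]],
          to = tabs$rotamer_ids[[i]][best], objective = cand[best])
        idx[i] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(idx = idx,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble(pass = integer(), site_id = character(), from = character(),
                to = character(), objective = numeric()))
}

#' @export
print.multiscan_result <- function(x, ...) {
  cat(sprintf("<multiscan_result> mode %s, objective %.4f kcal/mol (DTSS %.4f + pair %.4f)\n",
              attr(x, "mode"), attr(x, "objective"),
              attr(x, "dtss_total"), attr(x, "pair_total")))
  NextMethod()
}

#' Compare scanned against crystallographic conformations
#'
#' For every site with a recorded crystal rotamer, reports the DTSS of the
#' scan-chosen conformation, the DTSS of the crystal conformation (scored
#' alone, without inter-residue interactions, as crystal conformations are
#' conventionally quoted) and their difference
#' `delta = DTSS_scan - DTSS_crystal`: the barrier change attributable to
#' side-chain reorganization.
#'
#' @param sites site tibble with `crystal_rotamer` ids.
#' @param scan a [multiscan()] result for the same sites.
#' @param pair a [species_pair()].
#' @param library the [rotamer_library()] used for the scan.
#' @param max_order CAMM truncation rank.
#' @return tibble with `site_id`, `type`, `rotamer_scan`, `rotamer_crystal`,
#'   `dtss_scan`, `dtss_crystal`, `delta`; totals in attribute `totals`.
#'   Sites without a crystal rotamer are skipped with a warning.
#' @export
crystal_vs_scan_report <- function(sites, scan, pair, library, max_order = 4) {
  sites <- as_tibble(sites)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    cr <- sites$crystal_rotamer[i]
    if (is.na(cr)) {
      warn(sprintf("Site %s has no crystal rotamer id; skipped.", sites$site_id[i]))
      next
    }
    srow <- which(scan$site_id == sites$site_id[i])
    if (length(srow) != 1) {
      warn(sprintf("Site %s absent from scan result; skipped.", sites$site_id[i]))
      next
    }
    d_crystal <- dtss(place_rotamer(sites[i, ], cr, library), pair,
                      max_order = max_order)
    rows[[length(rows) + 1L]] <- tibble(
      site_id = sites$site_id[i], type = sites$type[i],
      rotamer_scan = scan$rotamer_id[srow], rotamer_crystal = cr,
      dtss_scan = scan$dtss[srow], dtss_crystal = d_crystal,
      delta = scan$dtss[srow] - d_crystal)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(site_id = character(), type = character(), rotamer_scan = character(),
           rotamer_crystal = character(), dtss_scan = numeric(),
           dtss_crystal = numeric(), delta = numeric())
  attr(out, "totals") <- list(dtss_scan = sum(out$dtss_scan),
                              dtss_crystal = sum(out$dtss_crystal),
                              delta = sum(out$delta))
  out
}
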