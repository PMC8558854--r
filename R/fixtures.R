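## Deterministic synthetic fixtures and the brute-force Coulomb oracle.
##
## Every generator is a pure function of its integer seed: one seed feeds
## independent substreams (one per generator call), so fixtures are
## bit-reproducible and never interfere with the caller's RNG state.
## Fixtures use point-charge "molecules" whose atomic moments (from
## atomic_moments_from_point_charges) are exact, so the Coulomb double sum
## is an exact ground truth for every energy the package computes.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

substream <- function(seed, stream) {
  ((as.numeric(seed) %% 2147483647) * 7919 + stream * 104729) %% 2147483399 + 1
}

#' Exact Coulomb interaction energy between two point-charge sets
#'
#' The brute-force double sum `sum_ij q_i q_j / r_ij`, the single source
#' of truth the multipole machinery is tested against.
#'
#' @param charges_a,charges_b data frames with columns `q` (e) and
#'   `x`, `y`, `z` (bohr).
#' @return energy in hartree.
#' @export
coulomb_oracle <- function(charges_a, charges_b) {
  a <- as_tibble(charges_a); b <- as_tibble(charges_b)
  pa <- as.matrix(a[, c("x", "y", "z")]); pb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  sum(outer(a$q, b$q) / sqrt(pmax(d2, 0)))
}

#' Potential of a point-charge set at given points (direct sum)
#'
#' @param charges data frame with `q`, `x`, `y`, `z` (bohr).
#' @param points n x 3 matrix (bohr).
#' @return potentials in hartree/e.
#' @export
coulomb_potential <- function(charges, points) {
  charges <- as_tibble(charges)
  points <- if (is.matrix(points)) points else matrix(as.numeric(points), nrow = 1)
  vapply(seq_len(nrow(points)), function(i) {
    d <- sqrt((charges$x - points[i, 1])^2 + (charges$y - points[i, 2])^2 +
                (charges$z - points[i, 3])^2)
    sum(charges$q / d)
  }, 0)
}

#' A single point charge as a multipole set
#'
#' @param q charge (e).
#' @param pos length-3 position (bohr).
#' @param label atom label.
#' @return a one-atom monopole-only [multipole_set()].
#' @export
point_charge_set <- function(q, pos, label = "probe") {
  multipole_set(tibble(label = label, x = pos[1], y = pos[2], z = pos[3], m0 = q),
                fragment_id = label)
}

#' Random point-charge cluster with exact atomic moments
#'
#' @param seed integer seed.
#' @param n number of charges.
#' @param net_charge net charge (e); the last charge absorbs the residual.
#' @param extent half-width of the sampling cube (bohr).
#' @param n_centers number of expansion centers: 1 puts a single center at
#'   the cluster offset; more centers are sampled in the cube with charges
#'   assigned to the nearest.
#' @param offset length-3 shift of the whole cluster (bohr).
#' @param fragment_id fragment id of the resulting set.
#' @return list with `charges` (tibble `q`,`x`,`y`,`z`), `centers`,
#'   `assignment`, `radius` (max charge distance from the offset) and
#'   `set` (the exact [multipole_set()]).
#' @export
make_cluster <- function(seed, n = 6, net_charge = 0, extent = 1.5,
                         n_centers = 1, offset = c(0, 0, 0),
                         fragment_id = "cluster") {
  with_seed(substream(seed, 11), {
    pos <- matrix(runif(n * 3, -extent, extent), ncol = 3)
    pos <- sweep(pos, 2L, offset, "+")
    q <- runif(n, -1, 1)
    q <- q + (net_charge - sum(q)) / n  # spread the residual: no outlier charge
    charges <- tibble(q = q, x = pos[, 1], y = pos[, 2], z = pos[, 3])
    centers <- if (n_centers == 1) matrix(offset, 1, 3) else {
      sweep(matrix(runif(n_centers * 3, -extent, extent), ncol = 3), 2L, offset, "+")
    }
    d2 <- outer(rowSums(pos^2), rowSums(centers^2), "+") - 2 * pos %*% t(centers)
    assignment <- max.col(-d2)
    set <- atomic_moments_from_point_charges(charges, centers, assignment,
                                             fragment_id = fragment_id)
    list(charges = charges, centers = centers, assignment = assignment,
         radius = max(sqrt(rowSums(sweep(pos, 2L, offset)^2))),
         set = set)
  })
}

#' Synthetic substrate/transition-state pair with a planted charge shift
#'
#' Emulates the charge redistribution of a reaction step: the transition
#' state has the substrate's geometry with `shift_charge` e moved from the
#' first charge's position along `shift`. To leading order the TS-RS
#' difference is a point dipole `shift_charge * shift`, so the far-field
#' catalytic field follows the analytic `cos(theta)/r^2` dipole pattern
#' (available via attribute `diff_dipole` for checks).
#'
#' @param seed integer seed.
#' @param n,extent cluster size and half-width (bohr) of the substrate.
#' @param shift_charge charge moved (e); 0 gives TS identical to RS and an
#'   identically zero catalytic field.
#' @param shift displacement vector (bohr).
#' @param e_rs,e_ts optional bare energies (hartree) for `B0`.
#' @return a [species_pair()] with attributes `charges_rs`, `charges_ts`
#'   (exact point charges) and `diff_dipole`.
#' @export
make_reaction_pair <- function(seed, n = 8, extent = 1.5, shift_charge = 0.5,
                               shift = c(0, 0, 1), e_rs = NULL, e_ts = NULL) {
  cl <- make_cluster(seed, n = n, net_charge = 0, extent = extent,
                     fragment_id = "RS")
  charges_rs <- cl$charges
  charges_ts <- charges_rs
  if (shift_charge != 0) {
    charges_ts$q[1] <- charges_ts$q[1] - shift_charge
    charges_ts <- dplyr::bind_rows(charges_ts, tibble(
      q = shift_charge,
      x = charges_rs$x[1] + shift[1],
      y = charges_rs$y[1] + shift[2],
      z = charges_rs$z[1] + shift[3]))
  }
  rs <- cl$set
  ts <- atomic_moments_from_point_charges(charges_ts, cl$centers,
                                          rep(1L, nrow(charges_ts)),
                                          fragment_id = "TS")
  pair <- species_pair(rs, ts, e_rs = e_rs, e_ts = e_ts)
  attr(pair, "charges_rs") <- charges_rs
  attr(pair, "charges_ts") <- charges_ts
  attr(pair, "diff_dipole") <- shift_charge * shift
  pair
}

## ---- Rotamer-library fixtures -----------------------------------------

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Local-frame rotamer geometry: three neutral anchor atoms plus a charged
## tip orbiting above them; tip charge +q is balanced by -q on anchor A1,
## so rotamers are neutral polar fragments (as a polar side-chain tip is).
rotamer_local_set <- function(type, rotamer_id, theta, tip_charge) {
  ang <- BOHR_PER_ANGSTROM
  atoms <- tibble(
    label = c("A1", "A2", "A3", "TIP"),
    element = c("C", "C", "C", "O"),
    x = c(0, 1.5, 0, 2.0 * cos(theta)) * ang,
    y = c(0, 0, 1.5, 2.0 * sin(theta)) * ang,
    z = c(0, 0, 0, 2.0) * ang,
    m0 = c(-tip_charge, 0, 0, tip_charge))
  multipole_set(atoms, fragment_id = paste0(type, ":", rotamer_id),
                formal_charge = 0L)
}

#' Synthetic rotamer library, residue sites and planted optimum
#'
#' Builds `n_sites` residue sites around a synthetic reaction pair, each
#' with its own residue type and `k_rotamers` conformations that differ by
#' rigid rotation of a neutral charged-tip dipole. With `planted = TRUE`
#' the planted optimum is the per-site DTSS argmin, made a provable global
#' minimum of the full MULTISCAN objective by construction: sites are
#' maximally spread on the shell, and the reaction charge shift (which the
#' per-site DTSS values, and hence their gaps, scale in exactly linearly,
#' while inter-rotamer couplings do not depend on it at all) is scaled
#' until every site's gap between best and runner-up rotamer exceeds
#' `margin` plus the site's total coupling spread. Any assignment
#' deviating at s sites then costs at least `s * margin` kcal/mol more
#' than the planted one. With `planted = FALSE` sites are placed on a
#' typical active-site shell (8-15 angstrom) where couplings genuinely
#' shape the optimum, for optimizer stress tests.
#'
#' @param seed integer seed.
#' @param n_sites,k_rotamers instance size.
#' @param planted plant a recoverable optimum (see above)?
#' @param radius_ang shell radius (angstrom): a scalar when planted, a
#'   range when not.
#' @param tip_charge tip charge magnitude (e).
#' @param margin required planted-optimum margin (kcal/mol).
#' @return list with `library`, `sites`, `pair`, `truth` (named rotamer
#'   assignment when planted, else `NULL`), `margin` (guaranteed
#'   planted-optimum margin) and `tip_charge`.
#' @export
make_rotamer_library <- function(seed, n_sites = 3, k_rotamers = 4,
                                 planted = TRUE,
                                 radius_ang = if (planted) 10 else c(8, 15),
                                 tip_charge = if (planted) 0.5 else 0.4,
                                 margin = 0.5) {
  with_seed(substream(seed, 22), {
    dirs <- if (planted) {
      base <- fibonacci_directions(max(n_sites, 3))[seq_len(n_sites), , drop = FALSE]
      base %*% t(random_rotation())
    } else {
      d <- matrix(rnorm(n_sites * 3), ncol = 3)
      d / sqrt(rowSums(d^2))
    }
    radii <- if (length(radius_ang) == 1) rep(radius_ang, n_sites) else {
      runif(n_sites, radius_ang[1], radius_ang[2])
    }
    phases <- runif(n_sites, 0, 2 * pi)
    frames <- replicate(n_sites, random_rotation(), simplify = FALSE)
    crystal <- sample.int(k_rotamers, n_sites, replace = TRUE)
    pair_seed <- substream(seed, 21)

    rows <- list(); anchors <- list(); site_rows <- list()
    local_anchor <- cbind(x = c(0, 1.5, 0), y = c(0, 0, 1.5), z = c(0, 0, 0))
    for (i in seq_len(n_sites)) {
      type <- sprintf("SC%d", i)
      anchors[[type]] <- c("A1", "A2", "A3")
      for (r in seq_len(k_rotamers)) {
        theta <- phases[i] + 2 * pi * (r - 1) / k_rotamers
        rows[[length(rows) + 1L]] <- tibble(
          type = type, rotamer_id = sprintf("rot%d", r),
          atoms = list(rotamer_local_set(type, sprintf("rot%d", r),
                                         theta, tip_charge)))
      }
      pos <- dirs[i, ] * radii[i]
      glob <- sweep(local_anchor %*% t(frames[[i]]), 2L, pos, "+")
      site_rows[[i]] <- residue_site(
        type = type,
        anchors = tibble(atom = c("A1", "A2", "A3"),
                         x = glob[, 1], y = glob[, 2], z = glob[, 3]),
        site_id = sprintf("site%d", i),
        crystal_rotamer = sprintf("rot%d", crystal[i]))
    }
    fx <- list(library = rotamer_library(dplyr::bind_rows(rows), anchors),
               sites = dplyr::bind_rows(site_rows))

    make_pair <- function(shift_charge) {
      make_reaction_pair(pair_seed, shift_charge = shift_charge,
                         shift = c(0, 0, 4))
    }
    pair <- make_pair(1)
    truth <- NULL; achieved <- NA_real_
    if (planted) {
      placements <- lapply(seq_len(n_sites), function(i) {
        lapply(seq_len(k_rotamers), function(r) {
          place_rotamer(fx$sites[i, ], sprintf("rot%d", r), fx$library)
        })
      })
      gaps <- numeric(n_sites); best <- character(n_sites)
      for (i in seq_len(n_sites)) {
        vals <- vapply(placements[[i]], dtss, 0, pair = pair)
        ord <- order(vals)
        gaps[i] <- vals[ord[2]] - vals[ord[1]]
        best[i] <- sprintf("rot%d", ord[1])
      }
      ## per-site coupling spread: how much the pairwise term can change
      ## when only this site's rotamer changes
      spread <- numeric(n_sites)
      if (n_sites > 1) {
        for (i in seq_len(n_sites - 1)) for (j in seq(i + 1, n_sites)) {
          e <- outer(seq_len(k_rotamers), seq_len(k_rotamers),
                     Vectorize(function(ri, rj) {
                       pair_energy(placements[[i]][[ri]], placements[[j]][[rj]]) *
                         HARTREE_TO_KCAL
                     }))
          d <- max(e) - min(e)
          spread[i] <- spread[i] + d
          spread[j] <- spread[j] + d
        }
      }
      ## DTSS (hence each gap) is exactly linear in the planted charge
      ## shift; couplings are independent of it
      need <- margin + max(spread)
      f <- max(1, 1.05 * need / min(gaps))
      pair <- make_pair(f)
      gaps <- gaps * f
      truth <- setNames(best, fx$sites$site_id)
      achieved <- min(gaps) - max(spread)
    }
    c(fx, list(pair = pair, truth = truth, margin = achieved,
               tip_charge = tip_charge))
  })
}

#' Coupled MULTISCAN stress instance
#'
#' [make_rotamer_library()] with `planted = FALSE`: sites on the 8-15
#' angstrom active-site shell where inter-rotamer couplings genuinely
#' shape the optimum.
#'
#' @inheritParams make_rotamer_library
#' @return as [make_rotamer_library()] (no planted truth).
#' @export
make_scan_instance <- function(seed, n_sites = 3, k_rotamers = 4, ...) {
  make_rotamer_library(seed, n_sites = n_sites, k_rotamers = k_rotamers,
                       planted = FALSE, ...)
}

## ---- Alignment and ensemble fixtures ----------------------------------

#' Toy multiple alignment with planted conserved charged columns
#'
#' @param seed integer seed.
#' @param n_seq number of sequences.
#' @param length alignment length.
#' @param n_conserved number of planted conserved charged columns
#'   (alternating negative/positive classes).
#' @param gap_fraction per-cell gap probability outside planted columns.
#' @return list with `alignment` (named character vector),
#'   `conserved_positions` and `classes`.
#' @export
make_toy_alignment <- function(seed, n_seq = 12, length = 60, n_conserved = 9,
                               gap_fraction = 0.02) {
  with_seed(substream(seed, 31), {
    neutral <- c("A", "G", "S", "T", "V", "L", "I", "F", "N", "Q", "M", "W", "Y", "P")
    mat <- matrix(sample(neutral, n_seq * length, replace = TRUE), nrow = n_seq)
    gaps <- matrix(runif(n_seq * length) < gap_fraction, nrow = n_seq)
    mat[gaps] <- "-"
    ## sprinkle charged letters without ever completing a charged column
    for (j in seq_len(length)) {
      kch <- sample(0:(n_seq - 1), 1, prob = c(0.7, rep(0.3 / (n_seq - 1), n_seq - 1)))
      if (kch > 0) {
        rows <- sample.int(n_seq, kch)
        mat[rows, j] <- sample(c("D", "E", "R", "K"), kch, replace = TRUE)
      }
    }
    positions <- sort(sample.int(length, n_conserved))
    classes <- rep(c("negative", "positive"), length.out = n_conserved)
    for (t in seq_len(n_conserved)) {
      pool <- if (classes[t] == "negative") NEGATIVE_AA else POSITIVE_AA
      mat[, positions[t]] <- sample(pool, n_seq, replace = TRUE)
    }
    ## ensure no accidental fully conserved charged column elsewhere
    for (j in setdiff(seq_len(length), positions)) {
      col <- mat[, j]
      if (all(col %in% NEGATIVE_AA) || all(col %in% POSITIVE_AA)) {
        mat[1, j] <- "A"
      }
    }
    alignment <- setNames(apply(mat, 1L, paste, collapse = ""),
                          sprintf("seq%02d", seq_len(n_seq)))
    list(alignment = alignment, conserved_positions = positions,
         classes = classes)
  })
}

#' Synthetic superposed ensemble with mobile side-chain tips
#'
#' Generates `n_structures` copies of a toy backbone whose C-alpha atoms
#' jitter with standard deviation `sigma_ca` per coordinate and whose
#' side-chain terminal (Ct) atoms jitter `ct_factor` times more, emulating
#' flexible charged side chains on a rigid fold.
#'
#' @param seed integer seed.
#' @param n_structures ensemble size (>= 2).
#' @param n_residues residues per structure (types cycle over
#'   Arg/Lys/Asp/Glu).
#' @param sigma_ca C-alpha jitter sd (angstrom, per coordinate).
#' @param ct_factor ratio of Ct to C-alpha jitter.
#' @return list with `ensemble` (list of [coord_set()]), `sigma_ca`,
#'   `ct_factor`.
#' @export
make_flexibility_ensemble <- function(seed, n_structures = 12, n_residues = 9,
                                      sigma_ca = 0.3, ct_factor = 3) {
  with_seed(substream(seed, 41), {
    types <- rep(names(CT_ATOM), length.out = n_residues)
    base_ca <- matrix(runif(n_residues * 3, -15, 15), ncol = 3)
    tip_dir <- matrix(rnorm(n_residues * 3), ncol = 3)
    tip_dir <- tip_dir / sqrt(rowSums(tip_dir^2))
    base_ct <- base_ca + 3.5 * tip_dir
    ensemble <- lapply(seq_len(n_structures), function(s) {
      ca <- base_ca + matrix(rnorm(n_residues * 3, sd = sigma_ca), ncol = 3)
      ct <- base_ct + matrix(rnorm(n_residues * 3, sd = ct_factor * sigma_ca), ncol = 3)
      rows <- lapply(seq_len(n_residues), function(i) {
        tibble(chain = "A", resno = i, resid = types[i],
               atom = c("CA", CT_ATOM[[types[i]]]),
               x = c(ca[i, 1], ct[i, 1]), y = c(ca[i, 2], ct[i, 2]),
               z = c(ca[i, 3], ct[i, 3]))
      })
      coord_set(dplyr::bind_rows(rows))
    })
    list(ensemble = ensemble, sigma_ca = sigma_ca, ct_factor = ct_factor)
  })
}

#' Write a complete demonstration workspace of synthetic inputs
#'
#' Emits every input class the package consumes: RS/TS multipole files, an
#' environment fragment, a rotamer library with residue sites, an aligned
#' FASTA and a small PDB, all generated from one seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named character vector of the files written, invisibly.
#' @export
write_fixture_workspace <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pair <- make_reaction_pair(seed, e_rs = 0, e_ts = 0.03)
  env <- make_cluster(substream(seed, 51), n = 5, net_charge = -1,
                      offset = c(0, 0, 12), fragment_id = "ENV")$set
  fx <- make_rotamer_library(seed)
  aln <- make_toy_alignment(seed)
  ens <- make_flexibility_ensemble(seed)
  paths <- c(
    rs = file.path(dir, "rs.multipole.json"),
    ts = file.path(dir, "ts.multipole.json"),
    env = file.path(dir, "env.multipole.json"),
    rotamers = file.path(dir, "rotamers.json"),
    sites = file.path(dir, "sites.json"),
    alignment = file.path(dir, "alignment.fasta"),
    pdb = file.path(dir, "ensemble0.pdb"))
  write_multipole_file(pair$rs, paths["rs"])
  write_multipole_file(pair$ts, paths["ts"])
  write_multipole_file(env, paths["env"])
  write_rotamer_library(fx$library, paths["rotamers"])
  write_sites_json(fx$sites, paths["sites"])
  writeLines(paste0(">", names(aln$alignment), "\n", aln$alignment),
             paths["alignment"])
  cs <- as_tibble(ens$ensemble[[1]])
  bio3d::write.pdb(file = paths["pdb"],
                   xyz = as.numeric(t(as.matrix(cs[, c("x", "y", "z")]))),
                   resno = cs$resno, chain = cs$chain, resid = cs$resid,
                   elety = cs$atom, eleno = seq_len(nrow(cs)))
  invisible(paths)
}
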