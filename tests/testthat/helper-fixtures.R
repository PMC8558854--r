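# Shared helpers: independent oracles and small constructors used across
# the suite. Oracles here deliberately avoid the code paths they check.

KCAL <- 627.5095
A2B <- catfield:::BOHR_PER_ANGSTROM   # bohr per angstrom
B2A <- catfield:::ANGSTROM_PER_BOHR

# internal accessors used when asserting on raw numbers
moment_matrix <- catfield:::moment_matrix
center_matrix <- catfield:::center_matrix

random_proper_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Independent brute-force MULTISCAN oracle: enumerates every assignment
# with its own loops over dtss()/pair_energy() values, lexicographic
# tie-break by construction order. Never calls multiscan() or its tables.
brute_force_scan <- function(sites, library, pair, max_order = 4) {
  n <- nrow(sites)
  placements <- lapply(seq_len(n), function(i) {
    ids <- library$rotamer_id[library$type == sites$type[i]]
    pl <- lapply(ids, function(rid) place_rotamer(sites[i, ], rid, library))
    names(pl) <- ids
    pl
  })
  d <- lapply(placements, function(pl) {
    vapply(pl, dtss, 0, pair = pair, max_order = max_order)
  })
  k <- lengths(placements)
  best_idx <- NULL
  best_J <- Inf
  idx <- rep(1L, n)
  repeat {
    J <- sum(vapply(seq_len(n), function(i) d[[i]][idx[i]], 0))
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        J <- J + KCAL * pair_energy(placements[[i]][[idx[i]]],
                                    placements[[j]][[idx[j]]],
                                    max_order = max_order)
      }
    }
    if (J < best_J) {  # strict: first (lexicographically smallest) wins ties
      best_J <- J
      best_idx <- idx
    }
    # lexicographic increment, last site fastest
    pos <- n
    repeat {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= k[pos]) break
      idx[pos] <- 1L
      pos <- pos - 1L
      if (pos == 0L) break
    }
    if (pos == 0L) break
  }
  assignment <- vapply(seq_len(n), function(i) names(placements[[i]])[best_idx[i]], "")
  list(assignment = setNames(assignment, sites$site_id), objective = best_J)
}

# A pair of point-charge clusters emulating atom-centered CAMMs: each
# charge gets its own expansion center displaced by at most 0.25 bohr
# (the charge density an atomic center carries is local, sub-bohr scale).
# The fragments carry +-1 e net charge (interacting ionic groups) so the
# oracle energy is monopole-dominated and the relative error is
# well-conditioned; neutral random clusters can have near-cancelling
# totals that make a relative comparison meaningless.
make_oracle_dimer <- function(seed, separation_factor = 5, n = 5, extent = 1.5) {
  set.seed(seed)
  build <- function(net, fragment_id) {
    pos <- matrix(runif(n * 3, -extent, extent), ncol = 3)
    q <- runif(n, -1, 1)
    q <- q + (net - sum(q)) / n
    centers <- pos + matrix(runif(n * 3, -0.25, 0.25), ncol = 3)
    list(q = q, pos = pos, centers = centers,
         radius = max(sqrt(rowSums(pos^2))), fragment_id = fragment_id)
  }
  a <- build(1, "A")
  b <- build(-1, "B")
  radius <- max(a$radius, b$radius)
  sep <- separation_factor * radius
  b$pos[, 1] <- b$pos[, 1] + sep
  b$centers[, 1] <- b$centers[, 1] + sep
  as_charges <- function(cl) tibble::tibble(q = cl$q, x = cl$pos[, 1],
                                            y = cl$pos[, 2], z = cl$pos[, 3])
  as_set <- function(cl) atomic_moments_from_point_charges(
    as_charges(cl), cl$centers, seq_len(n), fragment_id = cl$fragment_id)
  list(charges_a = as_charges(a), charges_b = as_charges(b),
       set_a = as_set(a), set_b = as_set(b), radius = radius, separation = sep)
}
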