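## Multipole-multipole interaction energies and electrostatic potentials.
##
## The expansion used throughout is the standard traced Cartesian form
##   E = sum over atom pairs, sum over k_a + k_b <= max_order of
##       (-1)^{k_a} / (k_a! k_b!)  M_a^{(k_a)} . T^{(k_a+k_b)}(R_ab) . M_b^{(k_b)}
## with R_ab pointing from the a-center to the b-center. The k_a = k_b = 0
## term is q_a q_b / R; for exact point-multipole inputs the series
## converges to the direct Coulomb sum with separation and order.

min_interset_distance <- function(ca, cb) {
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  sqrt(max(0, min(d2)))
}

#' CAMM interaction energy between two multipole sets
#'
#' Sums all multipole-multipole contraction terms with combined rank
#' `k_a + k_b <= max_order` over every pair of expansion centers. The
#' default truncation at combined rank 4 keeps interaction-tensor terms up
#' to the `1/R^5` distance dependence, the usual working accuracy of the
#' CAMM expansion (about 5% at equilibrium contact distances, far better
#' at long range).
#'
#' @param a,b [multipole_set()] objects sharing a coordinate frame.
#' @param max_order highest combined moment rank kept (0-4, default 4).
#' @return interaction energy in hartree.
#' @examples
#' q1 <- multipole_set(tibble::tibble(label = "a", x = 0, y = 0, z = 0, m0 = 1))
#' q2 <- multipole_set(tibble::tibble(label = "b", x = 0, y = 0, z = 2, m0 = 1))
#' pair_energy(q1, q2)  # 0.5 hartree
#' @export
pair_energy <- function(a, b, max_order = 4) {
  assert_multipole_set(a, "a"); assert_multipole_set(b, "b")
  max_order <- check_max_order(max_order)
  ca <- center_matrix(a); cb <- center_matrix(b)
  ia <- rep(seq_len(nrow(a)), times = nrow(b))
  ib <- rep(seq_len(nrow(b)), each = nrow(a))
  Rm <- cb[ib, , drop = FALSE] - ca[ia, , drop = FALSE]
  dist <- sqrt(rowSums(Rm^2))
  if (any(dist <= COINCIDENCE_TOL_BOHR)) {
    bad <- which.min(dist)
    abort(sprintf(
      "Coincident centers between fragments \"%s\" and \"%s\": atoms %s and %s.",
      fragment_id(a), fragment_id(b), a$label[ia[bad]], b$label[ib[bad]]),
      class = "catfield_coincident_centers")
  }
  Tcat <- eval_tensor_cat(Rm, max_order)
  tab <- pair_contraction_table()
  tab <- tab[tab[, "ktot"] <= max_order, , drop = FALSE]
  Ma <- moment_matrix(a)[ia, , drop = FALSE]
  Mb <- moment_matrix(b)[ib, , drop = FALSE]
  ## all contraction terms at once: n_pairs x n_terms products
  prods <- Ma[, tab[, "ia"], drop = FALSE] *
    Mb[, tab[, "ib"], drop = FALSE] * Tcat[, tab[, "it"], drop = FALSE]
  sum(prods %*% tab[, "w"])
}

check_max_order <- function(max_order) {
  if (length(max_order) != 1 || max_order != round(max_order) || max_order < 0) {
    abort("`max_order` must be a single non-negative integer.")
  }
  if (max_order > 4) {
    abort("`max_order` above 4 is unsupported: moments are carried to rank 4 only.",
          class = "catfield_unsupported_order")
  }
  as.integer(max_order)
}

#' Electrostatic potential of a multipole set
#'
#' Evaluates the multipole-expanded molecular electrostatic potential at
#' one or more points. The contract with [pair_energy()] is exact at every
#' truncation order: placing a unit point charge at `point` and calling
#' `pair_energy()` returns the same value.
#'
#' @param m a [multipole_set()].
#' @param point numeric length-3 vector or an n x 3 matrix of evaluation
#'   points (bohr).
#' @param max_order highest moment rank used (0-4, default 4).
#' @return potential(s) in hartree/e, one per point.
#' @examples
#' q <- multipole_set(tibble::tibble(label = "a", x = 0, y = 0, z = 0, m0 = 2))
#' potential(q, c(0, 0, 4))  # 0.5
#' @export
potential <- function(m, point, max_order = 4) {
  assert_multipole_set(m)
  max_order <- check_max_order(max_order)
  pts <- if (is.matrix(point)) point else matrix(as.numeric(point), nrow = 1L)
  if (ncol(pts) != 3) abort("`point` must have three coordinates.")
  centers <- center_matrix(m)
  mom <- moment_matrix(m)
  tab <- potential_contraction_table()
  tab <- tab[tab[, "k"] <= max_order, , drop = FALSE]
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(m))) {
    Rm <- sweep(pts, 2L, centers[i, ], "-")
    dist <- sqrt(rowSums(Rm^2))
    if (any(dist <= COINCIDENCE_TOL_BOHR)) {
      abort(sprintf("Evaluation point coincides with expansion center %s of \"%s\".",
                    m$label[i], fragment_id(m)),
            class = "catfield_coincident_centers")
    }
    Tcat <- eval_tensor_cat(Rm, max_order)
    im <- tab[, "im"]
    out <- out + as.numeric(Tcat[, im, drop = FALSE] %*% (tab[, "w"] * mom[i, im]))
  }
  out
}
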