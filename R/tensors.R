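## Cartesian interaction tensors T^(n) = grad^n (1/|R|) and the
## contraction tables used by pair_energy()/potential().
##
## Totally symmetric rank-n tensors are stored as their unique components,
## ordered by lexicographic non-decreasing index tuples over (x, y, z):
## rank 2 -> xx, xy, xz, yy, yz, zz, etc. A full contraction with another
## symmetric tensor is then a weighted sum over unique components with
## multinomial multiplicities.

.catfield_cache <- new.env(parent = emptyenv())

AXES <- c("x", "y", "z")
MOMENT_RANKS <- 0:4

#' Unique index tuples of a totally symmetric rank-k tensor
#'
#' @param k tensor rank (0 or more).
#' @return integer matrix with `k` columns; one row per unique component,
#'   rows in lexicographic order, entries in 1:3.
#' @keywords internal
#' @noRd
moment_tuples <- function(k) {
  key <- paste0("tuples_", k)
  if (!is.null(.catfield_cache[[key]])) return(.catfield_cache[[key]])
  if (k == 0) {
    out <- matrix(integer(), nrow = 1L, ncol = 0L)
  } else {
    grid <- as.matrix(expand.grid(rep(list(1:3), k)))[, k:1, drop = FALSE]
    keep <- apply(grid, 1L, function(t) all(diff(t) >= 0))
    out <- grid[keep, , drop = FALSE]
    dimnames(out) <- NULL
    out <- out[order(apply(out, 1L, paste, collapse = "")), , drop = FALSE]
  }
  .catfield_cache[[key]] <- out
  out
}

n_unique <- function(k) nrow(moment_tuples(k))

tuple_multiplicity <- function(tuple) {
  k <- length(tuple)
  counts <- tabulate(tuple, nbins = 3L)
  factorial(k) / prod(factorial(counts))
}

#' Column names for moments of a given rank ("m2_xy" etc.)
#' @noRd
moment_col_names <- function(k) {
  if (k == 0) return("m0")
  tl <- apply(moment_tuples(k), 1L, function(t) paste(AXES[t], collapse = ""))
  paste0("m", k, "_", tl)
}

moment_col_names_all <- function() {
  unlist(lapply(MOMENT_RANKS, moment_col_names), use.names = FALSE)
}

## Offset of rank k's first component within the concatenated 35-vector.
rank_offset <- function(k) sum(vapply(seq_len(k), function(j) n_unique(j - 1L), 1)) * (k > 0)

double_factorial <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

## ---- Term tables for T^(n) components ---------------------------------

## Each unique component of T^(n) is a sum of terms
##   coef * Rx^ex * Ry^ey * Rz^ez / |R|^p
## obtained from the pairing expansion of grad^n (1/R): a pairing with m
## Kronecker deltas contributes (-1)^(n+m) (2n-2m-1)!! / R^(2n-2m+1) and
## survives only if each paired position pair carries equal indices.
tensor_terms <- function(order) {
  key <- paste0("terms_", order)
  if (!is.null(.catfield_cache[[key]])) return(.catfield_cache[[key]])
  tuples <- moment_tuples(order)
  out <- vector("list", nrow(tuples))
  for (ci in seq_len(nrow(tuples))) {
    tuple <- tuples[ci, ]
    acc <- list()
    recurse <- function(remaining, m, free) {
      if (!length(remaining)) {
        ex <- tabulate(free, nbins = 3L)
        p <- 2L * order - 2L * m + 1L
        coef <- (-1)^(order + m) * double_factorial(2L * order - 2L * m - 1L)
        key2 <- paste(p, ex[1], ex[2], ex[3], sep = "_")
        prev <- acc[[key2]]
        acc[[key2]] <<- if (is.null(prev)) c(coef, p, ex) else prev + c(coef, 0, 0, 0, 0)
        return(invisible())
      }
      i <- remaining[1]
      rest <- remaining[-1]
      recurse(rest, m, c(free, tuple[i]))
      for (j in rest) {
        if (tuple[j] == tuple[i]) recurse(setdiff(rest, j), m + 1L, free)
      }
    }
    recurse(seq_len(order), 0L, integer())
    tab <- do.call(rbind, acc)
    tab <- tab[tab[, 1] != 0, , drop = FALSE]
    colnames(tab) <- c("coef", "p", "ex", "ey", "ez")
    out[[ci]] <- tab
  }
  .catfield_cache[[key]] <- out
  out
}

## Evaluate unique components of T^(order) for many separations at once.
## Rm: n x 3 matrix of separations (bohr). Returns n x n_unique(order).
eval_tensor_components <- function(Rm, order) {
  Rn <- sqrt(rowSums(Rm^2))
  terms <- tensor_terms(order)
  out <- matrix(0, nrow = nrow(Rm), ncol = length(terms))
  for (ci in seq_along(terms)) {
    tab <- terms[[ci]]
    acc <- 0
    for (ti in seq_len(nrow(tab))) {
      v <- tab[ti, "coef"] / Rn^tab[ti, "p"]
      if (tab[ti, "ex"] > 0) v <- v * Rm[, 1]^tab[ti, "ex"]
      if (tab[ti, "ey"] > 0) v <- v * Rm[, 2]^tab[ti, "ey"]
      if (tab[ti, "ez"] > 0) v <- v * Rm[, 3]^tab[ti, "ez"]
      acc <- acc + v
    }
    out[, ci] <- acc
  }
  out
}

## Concatenated unique components of T^(0..max_order): n x Sum n_unique(k).
eval_tensor_cat <- function(Rm, max_order) {
  do.call(cbind, lapply(0:max_order, function(k) eval_tensor_components(Rm, k)))
}

## ---- Public tensor constructor ----------------------------------------

#' Cartesian interaction tensor of 1/|R|
#'
#' Computes the rank-`order` tensor of partial derivatives of `1/|R|` with
#' respect to the components of the separation vector. These tensors mediate
#' multipole-multipole interaction energies: the charge-charge term uses
#' order 0 (`1/R`), charge-dipole order 1 (`-R/R^3`), dipole-dipole order 2
#' (`(3 R R - R^2 I)/R^5`), and so on. They are totally symmetric and, for
#' order >= 2, traceless in every index pair.
#'
#' @param separation numeric length-3 vector, the separation `R` in bohr
#'   (pointing from the first center to the second).
#' @param order tensor order, an integer from 0 to 8.
#' @return an object of class `interaction_tensor`: a list with elements
#'   `order`, `separation`, `components` (the full `3^order` array; a scalar
#'   for order 0) and `unique` (named vector of unique components).
#' @examples
#' interaction_tensor(c(2, 0, 0), 0)$components  # 1/R = 0.5
#' interaction_tensor(c(0, 0, 1), 2)$components  # diag(-1, -1, 2)
#' @export
interaction_tensor <- function(separation, order) {
  separation <- as.numeric(separation)
  if (length(separation) != 3 || any(!is.finite(separation))) {
    abort("`separation` must be a finite length-3 numeric vector.")
  }
  if (sqrt(sum(separation^2)) <= COINCIDENCE_TOL_BOHR) {
    abort("Coincident centers: |separation| is below the coincidence tolerance.",
          class = "catfield_coincident_centers")
  }
  if (length(order) != 1 || order != round(order) || order < 0 || order > 8) {
    abort("`order` must be a single integer between 0 and 8.",
          class = "catfield_unsupported_order")
  }
  order <- as.integer(order)
  uniq <- drop(eval_tensor_components(matrix(separation, nrow = 1L), order))
  names(uniq) <- if (order == 0) "T" else {
    apply(moment_tuples(order), 1L, function(t) paste(AXES[t], collapse = ""))
  }
  components <- unique_to_full(uniq, order)
  structure(
    list(order = order, separation = separation,
         components = components, unique = uniq),
    class = "interaction_tensor"
  )
}

#' @export
print.interaction_tensor <- function(x, ...) {
  cat("<interaction_tensor> order", x$order,
      "at separation (", paste(signif(x$separation, 6), collapse = ", "), ") bohr\n")
  print(x$unique)
  invisible(x)
}

## Expand unique components to the full symmetric array (index maps cached).
unique_to_full <- function(uniq, k) {
  if (k == 0) return(unname(uniq[1]))
  key <- paste0("u2f_", k)
  map <- .catfield_cache[[key]]
  if (is.null(map)) {
    full_idx <- as.matrix(expand.grid(rep(list(1:3), k)))
    keys <- apply(full_idx, 1L, function(t) paste(sort(t), collapse = ""))
    ukeys <- apply(moment_tuples(k), 1L, paste, collapse = "")
    map <- match(keys, ukeys)
    .catfield_cache[[key]] <- map
  }
  out <- unname(uniq)[map]
  if (k > 1) dim(out) <- rep(3L, k)
  out
}

full_to_unique <- function(arr, k) {
  if (k == 0) return(as.numeric(arr))
  key <- paste0("f2u_", k)
  lin <- .catfield_cache[[key]]
  if (is.null(lin)) {
    tuples <- moment_tuples(k)
    lin <- as.integer(1 + (tuples - 1L) %*% 3L^(seq_len(k) - 1L))
    .catfield_cache[[key]] <- lin
  }
  as.numeric(arr)[lin]
}

## ---- Contraction tables -----------------------------------------------

## Table driving pair_energy(): one row per (unique a-component, unique
## b-component) product with k_a + k_b <= 4. Columns: global index into the
## 35-long moment vector of a (`ia`) and b (`ib`), global index into the
## concatenated T^(0..4) unique vector (`it`), total order `ktot`, and the
## weight (-1)^ka/(ka! kb!) * mult_a * mult_b * mult-free T lookup.
pair_contraction_table <- function() {
  if (!is.null(.catfield_cache$pair_table)) return(.catfield_cache$pair_table)
  rows <- list()
  for (ka in MOMENT_RANKS) {
    for (kb in MOMENT_RANKS) {
      if (ka + kb > 4) next
      ta <- moment_tuples(ka); tb <- moment_tuples(kb)
      tt <- moment_tuples(ka + kb)
      ttkeys <- apply(tt, 1L, paste, collapse = "")
      for (ia in seq_len(nrow(ta))) {
        mult_a <- tuple_multiplicity(ta[ia, ])
        for (ib in seq_len(nrow(tb))) {
          mult_b <- tuple_multiplicity(tb[ib, ])
          key <- paste(sort(c(ta[ia, ], tb[ib, ])), collapse = "")
          rows[[length(rows) + 1L]] <- c(
            ia = rank_offset(ka) + ia,
            ib = rank_offset(kb) + ib,
            it = rank_offset(ka + kb) + match(key, ttkeys),
            ktot = ka + kb,
            w = (-1)^ka / (factorial(ka) * factorial(kb)) * mult_a * mult_b
          )
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  .catfield_cache$pair_table <- tab
  tab
}

## Table driving potential(): V(P) = sum_k (-1)^k/k! M^(k) . T^(k)(P - c).
potential_contraction_table <- function() {
  if (!is.null(.catfield_cache$pot_table)) return(.catfield_cache$pot_table)
  rows <- list()
  for (k in MOMENT_RANKS) {
    tk <- moment_tuples(k)
    for (iu in seq_len(nrow(tk))) {
      rows[[length(rows) + 1L]] <- c(
        im = rank_offset(k) + iu,
        k = k,
        w = (-1)^k / factorial(k) * tuple_multiplicity(tk[iu, ])
      )
    }
  }
  tab <- do.call(rbind, rows)
  .catfield_cache$pot_table <- tab
  tab
}
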