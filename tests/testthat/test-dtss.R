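test_that("identical RS and TS give zero DTSS and an all-zero field", {
  pair <- make_reaction_pair(5, shift_charge = 0)
  env <- make_cluster(6, n = 4, offset = c(0, 0, 10))$set
  expect_equal(dtss(env, pair), 0, tolerance = 1e-12)
  g <- static_field(pair, spacing = 2, padding = 4)
  expect_true(all(abs(g$delta_s[!g$masked]) < 1e-12))
})

test_that("a planted charge shift reproduces the hand-computed Coulomb difference", {
  # RS: neutral +/- pair; TS: 0.5 e moved 1 bohr along +z from the + site
  ch_rs <- tibble::tibble(q = c(1, -1), x = 0, y = 0, z = c(0.5, -0.5))
  ch_ts <- tibble::tibble(q = c(0.5, -1, 0.5), x = 0, y = 0, z = c(0.5, -0.5, 1.5))
  rs <- atomic_moments_from_point_charges(ch_rs, as.matrix(ch_rs[, c("x", "y", "z")]),
                                          1:2, fragment_id = "RS")
  ts <- atomic_moments_from_point_charges(ch_ts, as.matrix(ch_ts[, c("x", "y", "z")]),
                                          1:3, fragment_id = "TS")
  pair <- species_pair(rs, ts)
  probe_pos <- c(0, 0, 10)
  # four relevant Coulomb terms by hand (the shared -1 e site cancels)
  hand <- (0.5 / 9.5 + 0.5 / 8.5 - 1 / 9.5) * KCAL
  expect_equal(dtss(point_charge_set(1, probe_pos), pair), hand, tolerance = 1e-9)
})

test_that("dtss and the static field satisfy the sign contract at grid nodes", {
  pair <- make_reaction_pair(13)
  g <- static_field(pair, origin = c(-3, -3, 2), spacing = 1.5, shape = c(4, 4, 3))
  live <- which(!g$masked)
  expect_gt(length(live), 20)
  for (i in live) {
    node <- c(g$x[i], g$y[i], g$z[i]) * A2B
    d <- dtss(point_charge_set(1, node), pair)
    expect_equal(d + g$delta_s[i], 0, tolerance = 1e-10)
  }
})

test_that("point-charge DTSS equals the monopole-only environment exactly", {
  pair <- make_reaction_pair(17)
  expect_equal(dtss_point_charge(point_charges(numeric(), matrix(0, 0, 3)), pair), 0)
  set.seed(99)
  pos <- matrix(rnorm(9, sd = 2) + c(0, 0, 9), 3, 3)
  q <- c(1, -0.5, 0.25)
  env_pc <- point_charges(q, pos, units = "bohr")
  env_mono <- atomic_moments_from_point_charges(
    tibble::tibble(q = q, x = pos[, 1], y = pos[, 2], z = pos[, 3]),
    pos, 1:3, fragment_id = "ENV")
  expect_equal(dtss_point_charge(env_pc, pair), dtss(env_mono, pair),
               tolerance = 1e-12)
  # single +1 e charge is V_TS - V_RS at its position
  p1 <- c(0, 0, 11)
  expect_equal(dtss_point_charge(point_charges(1, matrix(p1, 1), units = "bohr"), pair),
               (potential(pair$ts, p1) - potential(pair$rs, p1)) * KCAL,
               tolerance = 1e-12)
})

test_that("DTSS is additive over disjoint environment fragments", {
  pair <- make_reaction_pair(23)
  f1 <- make_cluster(24, n = 3, offset = c(10, 0, 0), fragment_id = "F1")$set
  f2 <- make_cluster(25, n = 3, offset = c(0, 12, 0), fragment_id = "F2")$set
  f3 <- make_cluster(26, n = 4, offset = c(-9, -5, 5), fragment_id = "F3")$set
  together <- bind_multipole_sets(f1, f2, f3, fragment_id = "ENV")
  expect_equal(dtss(together, pair),
               dtss(f1, pair) + dtss(f2, pair) + dtss(f3, pair),
               tolerance = 1e-10)
})

test_that("the field of a pure charge-displacement is antisymmetric about its midplane", {
  # TS = RS plus charge delta moved from z=0 to z=1 (bohr): the TS-RS
  # difference potential is odd under reflection through z = 0.5 bohr
  cl <- make_cluster(31, n = 5)
  ch_rs <- cl$charges
  ch_ts <- dplyr::bind_rows(ch_rs,
                            tibble::tibble(q = c(-0.5, 0.5), x = 0, y = 0, z = c(0, 1)))
  # one center per charge: the expansion (and hence the symmetry) is exact
  rs <- atomic_moments_from_point_charges(ch_rs, as.matrix(ch_rs[, c("x", "y", "z")]),
                                          seq_len(nrow(ch_rs)), fragment_id = "RS")
  ts <- atomic_moments_from_point_charges(ch_ts, as.matrix(ch_ts[, c("x", "y", "z")]),
                                          seq_len(nrow(ch_ts)), fragment_id = "TS")
  pair <- species_pair(rs, ts)
  zc <- 0.5 * B2A  # midplane in angstrom
  nz <- 4
  spacing <- 1.25
  origin <- c(-2, -2, zc - spacing * (nz - 1) / 2)
  g <- static_field(pair, origin = origin, spacing = spacing, shape = c(4, 4, nz))
  # pair node with its mirror in z
  key <- function(x, y, z) sprintf("%.6f_%.6f_%.6f", x, y, z)
  idx <- setNames(seq_len(nrow(g)), key(g$x, g$y, g$z))
  checked <- 0
  for (i in which(!g$masked)) {
    j <- idx[[key(g$x[i], g$y[i], 2 * zc - g$z[i])]]
    if (!is.null(j) && !g$masked[j]) {
      expect_equal(g$delta_s[i], -g$delta_s[j], tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("grid refinement keeps shared nodes bit-identical", {
  pair <- make_reaction_pair(37)
  origin <- c(-2, -2, 4)
  coarse <- static_field(pair, origin = origin, spacing = 2, shape = c(3, 3, 2))
  fine <- static_field(pair, origin = origin, spacing = 1, shape = c(5, 5, 3))
  fk <- sprintf("%.9f_%.9f_%.9f", fine$x, fine$y, fine$z)
  ck <- sprintf("%.9f_%.9f_%.9f", coarse$x, coarse$y, coarse$z)
  shared <- match(ck, fk)
  expect_false(anyNA(shared))
  expect_identical(coarse$delta_s, fine$delta_s[shared])
})

test_that("barrier estimates are plain additive arithmetic", {
  est <- barrier_estimate(18.95, c(a = -3.29, b = -3.29))
  expect_equal(est$total, 12.37)
  expect_equal(barrier_estimate(84)$total, 84)
  expect_equal(glance(est)$sum_dtss, -6.58)
  expect_equal(nrow(tidy(est)), 2)
  expect_error(barrier_estimate(NA_real_), "finite")
  expect_error(barrier_estimate(1, c(a = Inf)), "finite")
  # invariant: total re-derives from the stored pieces
  expect_equal(est$total, est$b0 + sum(est$contributions$dtss), tolerance = 1e-9)
})

test_that("static_field masks near-center nodes and validates its grid", {
  pair <- make_reaction_pair(41)
  g <- static_field(pair, origin = c(-0.2, -0.2, -0.2), spacing = 0.2,
                    shape = c(3, 3, 3))
  expect_true(any(g$masked))
  expect_true(all(is.na(g$delta_s[g$masked])))
  expect_error(static_field(pair, shape = c(0, 3, 3)), "grid")
  expect_error(static_field(pair, spacing = -1), "positive")
})
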