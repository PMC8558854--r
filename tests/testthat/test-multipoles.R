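test_that("exact moments of point charges follow the moment definition", {
  # charge exactly on its center: monopole only
  m <- atomic_moments_from_point_charges(
    tibble::tibble(q = 2, x = 1, y = -1, z = 0.5),
    matrix(c(1, -1, 0.5), 1, 3), 1L)
  expect_equal(m$m0, 2)
  mm <- moment_matrix <- as.matrix(m[, setdiff(grep("^m", names(m), value = TRUE), "m0")])
  expect_true(all(abs(mm) < 1e-14))

  # off-center charge: dipole and quadrupole by hand
  m2 <- atomic_moments_from_point_charges(
    tibble::tibble(q = 1, x = 0, y = 0, z = 0.5), matrix(0, 1, 3), 1L)
  expect_equal(m2$m1_z, 0.5)
  expect_equal(m2$m2_zz, 0.25)
  expect_equal(m2$m1_x, 0)
  expect_equal(m2$m2_xy, 0)

  expect_error(
    atomic_moments_from_point_charges(
      tibble::tibble(q = 1, x = 0, y = 0, z = 0), matrix(0, 1, 3), NA_integer_),
    "assigned")
})

test_that("total molecular moments are origin-consistent and partition-invariant", {
  # neutral +/- pair: dipole (0,0,1) regardless of origin
  ch <- tibble::tibble(q = c(1, -1), x = 0, y = 0, z = c(0.5, -0.5))
  np <- atomic_moments_from_point_charges(ch, matrix(0, 1, 3), c(1L, 1L))
  for (origin in list(c(0, 0, 0), c(3, -2, 5))) {
    tm <- total_molecular_moments(np, origin)
    expect_equal(tm$rank1, c(0, 0, 1), tolerance = 1e-12)
  }

  set.seed(5)
  ch10 <- tibble::tibble(q = runif(10, -1, 1),
                         x = runif(10, -1, 1), y = runif(10, -1, 1), z = runif(10, -1, 1))
  centers <- matrix(runif(9, -1, 1), 3, 3)
  m_a <- atomic_moments_from_point_charges(ch10, centers, rep(1:3, length.out = 10))
  m_b <- atomic_moments_from_point_charges(ch10, centers, rep(3:1, length.out = 10))
  ta <- attr(total_molecular_moments(m_a, c(0.2, 0.1, -0.3)), "unique")
  tb <- attr(total_molecular_moments(m_b, c(0.2, 0.1, -0.3)), "unique")
  expect_equal(ta, tb, tolerance = 1e-10)
  # total monopole equals the net charge
  expect_equal(unname(ta["m0"]), sum(ch10$q), tolerance = 1e-12)
  # total dipole equals sum q_i r_i about the origin
  t0 <- total_molecular_moments(m_a, c(0, 0, 0))
  expect_equal(t0$rank1, c(sum(ch10$q * ch10$x), sum(ch10$q * ch10$y),
                           sum(ch10$q * ch10$z)), tolerance = 1e-12)
})

test_that("translation preserves the far field and has the closed-form base case", {
  q <- multipole_set(tibble::tibble(label = "a", x = 0, y = 0, z = 0, m0 = 1))
  tr <- translate_moments(q, c(0, 0, 1))
  expect_equal(tr$m1_z, -1)
  expect_equal(tr$m0, 1)

  # identity translation
  same <- translate_moments(q, c(0, 0, 0))
  expect_equal(as.numeric(same[1, grep("^m", names(same))]),
               as.numeric(q[1, grep("^m", names(q))]))

  # a charged cluster keeps the far potential away from zero, so the
  # relative comparison probes the translation itself. A 2-bohr shift of a
  # rank-4 expansion loses information at the (d/R)^5 scale, about 1.3e-6
  # of the potential at 30 bohr, so the tolerance sits just above that
  # irreducible floor and a doubled distance must win back the factor 2^5.
  cl <- make_cluster(9, n = 6, extent = 0.8, net_charge = 1)$set
  tr <- translate_moments(cl, c(0, 0, 2))
  rel30 <- abs(potential(tr, c(0, 0, 30)) - potential(cl, c(0, 0, 30))) /
    abs(potential(cl, c(0, 0, 30)))
  rel60 <- abs(potential(tr, c(0, 0, 60)) - potential(cl, c(0, 0, 60))) /
    abs(potential(cl, c(0, 0, 60)))
  expect_lt(rel30, 1e-5)
  expect_lt(rel60, 1e-6)
  expect_lt(rel60, rel30 / 16)
})

test_that("rotation acts on centers and every tensor index", {
  dx <- multipole_set(tibble::tibble(label = "a", x = 0, y = 0, z = 0, m1_x = 1))
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  rd <- rotate_moments(dx, R90)
  expect_equal(c(rd$m1_x, rd$m1_y, rd$m1_z), c(0, 1, 0), tolerance = 1e-12)

  expect_equal(as.data.frame(rotate_moments(dx, diag(3))), as.data.frame(dx))

  expect_error(rotate_moments(dx, diag(3) * 1.1), class = "catfield_invalid_rotation")
  expect_error(rotate_moments(dx, diag(c(1, 1, -1))), class = "catfield_invalid_rotation")

  set.seed(21)
  a <- make_cluster(31, n = 5)$set
  b <- make_cluster(32, n = 5, offset = c(9, 0, 0))$set
  e0 <- pair_energy(a, b)
  R <- random_proper_rotation()
  expect_equal(pair_energy(rotate_moments(a, R), rotate_moments(b, R)), e0,
               tolerance = 1e-10)
})

test_that("multipole_set validates its invariants", {
  expect_error(
    multipole_set(tibble::tibble(label = c("a", "a"), x = 0:1, y = 0, z = 0, m0 = 0)),
    "unique")
  expect_error(
    multipole_set(tibble::tibble(label = "a", x = 0, y = 0, z = 0, m0 = 0.5),
                  formal_charge = 1),
    "formal_charge")
  # angstrom input lands in bohr
  m <- multipole_set(tibble::tibble(label = "a", x = 1, y = 0, z = 0, m0 = 1),
                     units = "angstrom")
  expect_equal(m$x, A2B, tolerance = 1e-12)
})
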