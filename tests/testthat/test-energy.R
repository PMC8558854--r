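test_that("pair energies reproduce the closed-form interaction families", {
  q1 <- multipole_set(tibble::tibble(label = "a", x = 0, y = 0, z = 0, m0 = 1))
  q2 <- multipole_set(tibble::tibble(label = "b", x = 0, y = 0, z = 2, m0 = 1))
  expect_equal(pair_energy(q1, q2), 0.5, tolerance = 1e-14)

  # charge-dipole: q at origin, mu = (0,0,1) at (0,0,2): E = -q mu / R^2
  d <- multipole_set(tibble::tibble(label = "b", x = 0, y = 0, z = 2, m1_z = 1))
  expect_equal(pair_energy(q1, d), -0.25, tolerance = 1e-14)

  # parallel dipoles along their axis: (mu.mu - 3 (mu.Rh)^2)/R^3 = -2
  d1 <- multipole_set(tibble::tibble(label = "a", x = 0, y = 0, z = 0, m1_z = 1))
  d2 <- multipole_set(tibble::tibble(label = "b", x = 0, y = 0, z = 1, m1_z = 1))
  expect_equal(pair_energy(d1, d2), -2, tolerance = 1e-14)
  # side-by-side parallel dipoles: +mu^2/R^3
  d3 <- multipole_set(tibble::tibble(label = "b", x = 1, y = 0, z = 0, m1_z = 1))
  expect_equal(pair_energy(d1, d3), 1, tolerance = 1e-14)
})

test_that("rank-4 truncation converges to the Coulomb oracle at separation", {
  errs5 <- errs10 <- errs20 <- numeric(20)
  for (s in 1:20) {
    dim5 <- make_oracle_dimer(s, separation_factor = 5)
    dim10 <- make_oracle_dimer(s, separation_factor = 10)
    dim20 <- make_oracle_dimer(s, separation_factor = 20)
    for (d in list(list(dim5, 1), list(dim10, 2), list(dim20, 3))) {
      oracle <- coulomb_oracle(d[[1]]$charges_a, d[[1]]$charges_b)
      e <- pair_energy(d[[1]]$set_a, d[[1]]$set_b, max_order = 4)
      rel <- abs(e - oracle) / abs(oracle)
      if (d[[2]] == 1) errs5[s] <- rel
      if (d[[2]] == 2) errs10[s] <- rel
      if (d[[2]] == 3) errs20[s] <- rel
    }
  }
  expect_lt(max(errs5), 1e-3)
  # error shrinks with separation (mean over seeds to absorb noise)
  expect_lt(mean(errs10), mean(errs5))
  expect_lt(mean(errs20), mean(errs10))
})

test_that("monopole-exact clusters agree with the oracle at any separation", {
  set.seed(3)
  for (s in 1:5) {
    a <- make_cluster(s, n = 4)
    b <- make_cluster(s + 50, n = 4, offset = c(4, 0.5, -0.5))
    # one center per charge: the expansion is exact
    ea <- atomic_moments_from_point_charges(a$charges,
                                            as.matrix(a$charges[, c("x", "y", "z")]),
                                            1:4, fragment_id = "A")
    eb <- atomic_moments_from_point_charges(b$charges,
                                            as.matrix(b$charges[, c("x", "y", "z")]),
                                            1:4, fragment_id = "B")
    oracle <- coulomb_oracle(a$charges, b$charges)
    expect_equal(pair_energy(ea, eb), oracle, tolerance = 1e-12)
    # and symmetric in its arguments
    expect_equal(pair_energy(ea, eb), pair_energy(eb, ea), tolerance = 1e-12)
  }
})

test_that("energies and potentials are invariant under common rigid motion", {
  a <- make_cluster(61, n = 5)$set
  b <- make_cluster(62, n = 5, offset = c(8, 1, 0))$set
  e0 <- pair_energy(a, b)
  set.seed(7)
  for (rep in 1:3) {
    R <- random_proper_rotation()
    t_vec <- rnorm(3, sd = 5)
    am <- catfield:::transform_multipole_set(a, R, t_vec)
    bm <- catfield:::transform_multipole_set(b, R, t_vec)
    expect_equal(pair_energy(am, bm), e0, tolerance = 1e-10)
    pt <- c(1, 2, 12)
    expect_equal(potential(am, as.numeric(R %*% pt + t_vec)), potential(a, pt),
                 tolerance = 1e-10)
  }
})

test_that("potential is the unit-charge pair energy at every truncation order", {
  m <- make_cluster(71, n = 6)$set
  pt <- c(1.5, -2, 6)
  probe <- point_charge_set(1, pt)
  for (k in 0:4) {
    expect_equal(potential(m, pt, max_order = k),
                 pair_energy(m, probe, max_order = k), tolerance = 1e-14)
  }
  # far-point potential matches the direct sum
  cl <- make_cluster(72, n = 8)
  far <- c(0, 25, 5)
  expect_lt(abs(potential(cl$set, far) - coulomb_potential(cl$charges, far)) /
              abs(coulomb_potential(cl$charges, far)), 1e-3)
})

test_that("degenerate geometry and unsupported truncations are rejected", {
  a <- multipole_set(tibble::tibble(label = "a1", x = 0, y = 0, z = 0, m0 = 1),
                     fragment_id = "A")
  b <- multipole_set(tibble::tibble(label = "b1", x = 0, y = 0, z = 0, m0 = 1),
                     fragment_id = "B")
  err <- expect_error(pair_energy(a, b), class = "catfield_coincident_centers")
  expect_match(conditionMessage(err), "a1")
  expect_match(conditionMessage(err), "b1")
  expect_error(pair_energy(a, a, max_order = 5), class = "catfield_unsupported_order")
  expect_error(potential(a, c(0, 0, 0)), class = "catfield_coincident_centers")
})
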