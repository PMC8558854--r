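make_frame <- function(n = 6, seed = 1) {
  set.seed(seed)
  coord_set(tibble::tibble(atom = paste0("a", seq_len(n)),
                           x = rnorm(n, sd = 3), y = rnorm(n, sd = 3),
                           z = rnorm(n, sd = 3)))
}

test_that("superposition recovers exact transforms", {
  ref <- make_frame()
  s0 <- superpose(ref, ref)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s0$translation, c(0, 0, 0), tolerance = 1e-10)

  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  rotated <- ref
  xyz <- as.matrix(tibble::as_tibble(ref)[, c("x", "y", "z")]) %*% t(R90)
  rotated$x <- xyz[, 1]; rotated$y <- xyz[, 2]; rotated$z <- xyz[, 3]
  s1 <- superpose(rotated, ref)
  expect_equal(s1$rmsd, 0, tolerance = 1e-10)
  expect_equal(s1$rotation %*% R90, diag(3), tolerance = 1e-10)
})

test_that("rmsd matches direct recomputation on noisy copies", {
  ref <- make_frame(n = 20, seed = 2)
  set.seed(3)
  sigma <- 0.1
  noisy <- ref
  noisy$x <- noisy$x + rnorm(20, sd = sigma)
  noisy$y <- noisy$y + rnorm(20, sd = sigma)
  noisy$z <- noisy$z + rnorm(20, sd = sigma)
  s <- superpose(noisy, ref)
  # direct formula over the transformed coordinates
  A <- as.matrix(tibble::as_tibble(s$transformed)[, c("x", "y", "z")])
  B <- as.matrix(tibble::as_tibble(ref)[, c("x", "y", "z")])
  expect_equal(s$rmsd, sqrt(mean(rowSums((A - B)^2))), tolerance = 1e-12)
  # in the expected band for 3-coordinate gaussian noise
  expect_gt(s$rmsd, 0.5 * sigma)
  expect_lt(s$rmsd, 2 * sigma * sqrt(3))
})

test_that("superposition always returns a proper rotation, never a reflection", {
  for (seed in 1:10) {
    mobile <- make_frame(n = 4, seed = seed)
    ref <- make_frame(n = 4, seed = seed + 100)
    s <- superpose(mobile, ref)
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition rmsd is invariant under common rigid motion", {
  mobile <- make_frame(n = 8, seed = 5)
  ref <- make_frame(n = 8, seed = 6)
  base <- superpose(mobile, ref)$rmsd
  set.seed(7)
  R <- random_proper_rotation()
  t_vec <- rnorm(3, sd = 10)
  move <- function(cs) {
    xyz <- sweep(as.matrix(tibble::as_tibble(cs)[, c("x", "y", "z")]) %*% t(R), 2, t_vec, "+")
    cs$x <- xyz[, 1]; cs$y <- xyz[, 2]; cs$z <- xyz[, 3]
    cs
  }
  expect_equal(superpose(move(mobile), move(ref))$rmsd, base, tolerance = 1e-9)
})

test_that("superposition agrees with the bio3d reference implementation", {
  mobile <- make_frame(n = 10, seed = 8)
  ref <- make_frame(n = 10, seed = 9)
  s <- superpose(mobile, ref)
  xyz_m <- as.numeric(t(as.matrix(tibble::as_tibble(mobile)[, c("x", "y", "z")])))
  xyz_r <- as.numeric(t(as.matrix(tibble::as_tibble(ref)[, c("x", "y", "z")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_r, mobile = xyz_m))
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) -
       matrix(xyz_r, ncol = 3, byrow = TRUE))^2)))
  expect_equal(s$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("degenerate superposition inputs are rejected", {
  ref <- make_frame(n = 2)
  expect_error(superpose(ref, ref), "three")
  line <- coord_set(tibble::tibble(atom = c("a", "b", "c"),
                                   x = c(0, 1, 2), y = 0, z = 0))
  expect_error(superpose(line, line), "collinear|Degenerate")
})

test_that("flexibility statistics recover a planted mobility ratio", {
  fx <- make_flexibility_ensemble(11, n_structures = 12, n_residues = 9,
                                  sigma_ca = 0.3, ct_factor = 3)
  stats <- flexibility_stats(fx$ensemble)
  expect_equal(nrow(stats), 9)
  expect_true(all(stats$rmsd_ct > stats$rmsd_ca))
  expect_gt(mean(stats$ratio), 2.2)
  expect_lt(mean(stats$ratio), 3.8)

  # identical structures: both rmsds zero
  same <- flexibility_stats(list(fx$ensemble[[1]], fx$ensemble[[1]]))
  expect_true(all(same$rmsd_ca == 0))
  expect_true(all(same$rmsd_ct == 0))

  expect_error(flexibility_stats(fx$ensemble[1]), "at least two")

  # a residue missing its Ct atom in one structure is skipped with a warning
  broken <- fx$ensemble
  tab <- tibble::as_tibble(broken[[2]])
  broken[[2]] <- coord_set(tab[!(tab$resno == 1 & tab$atom != "CA"), ])
  expect_warning(st2 <- flexibility_stats(broken), "skipped")
  expect_equal(nrow(st2), 8)
})
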