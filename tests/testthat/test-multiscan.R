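# A minimal one-type library used by the placement tests: anchors A1-A3
# plus a dipolar tip, all monopole-only moments.
tiny_library <- function(tip = c(2, 0, 2)) {
  atoms <- tibble::tibble(
    label = c("A1", "A2", "A3", "TIP"),
    element = c("C", "C", "C", "O"),
    x = c(0, 1.5, 0, tip[1]) * A2B, y = c(0, 0, 1.5, tip[2]) * A2B,
    z = c(0, 0, 0, tip[3]) * A2B,
    m0 = c(-0.5, 0, 0, 0.5))
  rotamer_library(
    tibble::tibble(type = "SC", rotamer_id = "rot1",
                   atoms = list(multipole_set(atoms, fragment_id = "SC:rot1",
                                              formal_charge = 0L))),
    anchors = list(SC = c("A1", "A2", "A3")))
}

local_site <- function(anchors_xyz, id = "s1", crystal = NA_character_) {
  residue_site("SC", tibble::tibble(atom = c("A1", "A2", "A3"),
                                    x = anchors_xyz[, 1], y = anchors_xyz[, 2],
                                    z = anchors_xyz[, 3]),
               site_id = id, crystal_rotamer = crystal)
}

library_frame_anchors <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0))

test_that("placement at the library frame is the identity", {
  lib <- tiny_library()
  site <- local_site(library_frame_anchors)
  placed <- place_rotamer(site, "rot1", lib)
  expect_equal(attr(placed, "anchor_rmsd"), 0, tolerance = 1e-10)
  expect_equal(as.data.frame(placed[, -(1:2)]),
               as.data.frame(lib$atoms[[1]][, -(1:2)]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("placement rotates coordinates and moment tensors together", {
  # dipole moments on the tip atom to exercise tensor rotation
  atoms <- tibble::tibble(label = c("A1", "A2", "A3", "TIP"),
                          x = c(0, 1.5, 0, 2) * A2B, y = c(0, 0, 1.5, 0) * A2B,
                          z = c(0, 0, 0, 2) * A2B,
                          m1_x = c(0, 0, 0, 1))
  lib <- rotamer_library(
    tibble::tibble(type = "SC", rotamer_id = "rot1",
                   atoms = list(multipole_set(atoms, fragment_id = "SC:rot1"))),
    anchors = list(SC = c("A1", "A2", "A3")))
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  site <- local_site(library_frame_anchors %*% t(R90), id = "rot90")
  placed <- place_rotamer(site, "rot1", lib)
  tip <- placed[placed$label == "TIP", ]
  expect_equal(c(tip$m1_x, tip$m1_y, tip$m1_z), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(c(tip$x, tip$y, tip$z), as.numeric(R90 %*% (c(2, 0, 2) * A2B)),
               tolerance = 1e-10)
})

test_that("probe energies agree whichever frame hosts the superposition", {
  lib <- tiny_library()
  set.seed(31)
  R <- random_proper_rotation()
  t_ang <- rnorm(3, sd = 4)
  site <- local_site(sweep(library_frame_anchors %*% t(R), 2, t_ang, "+"))
  placed <- place_rotamer(site, "rot1", lib)
  probe_site <- c(5, 1, -2)  # bohr, site frame
  e_site <- pair_energy(placed, point_charge_set(1, probe_site))
  # rotate the probe back into the library frame instead
  probe_lib <- as.numeric(t(R) %*% (probe_site - t_ang * A2B))
  e_lib <- pair_energy(lib$atoms[[1]], point_charge_set(1, probe_lib))
  expect_equal(e_site, e_lib, tolerance = 1e-10)
})

test_that("collinear site anchors are rejected", {
  lib <- tiny_library()
  bad <- local_site(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(place_rotamer(bad, "rot1", lib), "collinear|Degenerate")
})

test_that("single-site scans return the DTSS argmin; far sites decouple", {
  fx <- make_rotamer_library(43, n_sites = 1, k_rotamers = 5)
  vals <- vapply(paste0("rot", 1:5), function(r) {
    dtss(place_rotamer(fx$sites[1, ], r, fx$library), fx$pair)
  }, 0)
  res <- multiscan(fx$sites, fx$library, fx$pair, mode = "exhaustive")
  expect_equal(res$rotamer_id, names(which.min(vals)))
  expect_equal(attr(res, "objective"), min(vals), tolerance = 1e-9)
  expect_equal(attr(res, "pair_total"), 0)

  # two neutral-dipole sites 60 angstrom apart: negligible pair term
  lib <- tiny_library()
  sites <- dplyr::bind_rows(
    local_site(sweep(library_frame_anchors, 2, c(0, 0, 25), "+"), id = "s1"),
    local_site(sweep(library_frame_anchors, 2, c(0, 0, -35), "+"), id = "s2"))
  sc <- scan_objective(c(s1 = "rot1", s2 = "rot1"), sites, lib,
                       make_reaction_pair(44))
  expect_lt(abs(sc$pair_total), 0.01)
})

test_that("the stored breakdown reproduces the objective", {
  fx <- make_scan_instance(47)
  asn <- setNames(c("rot2", "rot4", "rot1"), fx$sites$site_id)
  sc <- scan_objective(asn, fx$sites, fx$library, fx$pair)
  expect_equal(sc$objective, sum(sc$breakdown$dtss) + sum(sc$pair_energies$energy),
               tolerance = 1e-9)
  expect_equal(sc$dtss_total + sc$pair_total, sc$objective, tolerance = 1e-12)

  res <- multiscan(fx$sites, fx$library, fx$pair, mode = "exhaustive")
  expect_equal(attr(res, "objective"),
               sum(res$dtss) + sum(attr(res, "pair_energies")$energy),
               tolerance = 1e-9)
})

test_that("exhaustive search equals the independent brute-force oracle", {
  for (seed in 1:20) {
    fx <- make_scan_instance(seed)
    res <- multiscan(fx$sites, fx$library, fx$pair, mode = "exhaustive")
    oracle <- brute_force_scan(fx$sites, fx$library, fx$pair)
    expect_identical(setNames(res$rotamer_id, res$site_id), oracle$assignment)
    expect_equal(attr(res, "objective"), oracle$objective, tolerance = 1e-9)
  }
})

test_that("planted optima are recovered and site order is irrelevant", {
  for (seed in 1:20) {
    fx <- make_rotamer_library(seed)
    expect_gte(fx$margin, 0.5)
    res <- multiscan(fx$sites, fx$library, fx$pair, mode = "exhaustive")
    expect_identical(setNames(res$rotamer_id, res$site_id), fx$truth)
  }
  fx <- make_rotamer_library(101)
  res <- multiscan(fx$sites, fx$library, fx$pair, mode = "exhaustive")
  perm <- c(3, 1, 2)
  res_p <- multiscan(fx$sites[perm, ], fx$library, fx$pair, mode = "exhaustive")
  expect_identical(res$rotamer_id[perm], res_p$rotamer_id)
  expect_identical(attr(res, "objective"), attr(res_p, "objective"))
})

test_that("iterative mode terminates at or above the exhaustive optimum", {
  for (seed in 1:10) {
    fx <- make_scan_instance(seed + 200)
    rE <- multiscan(fx$sites, fx$library, fx$pair, mode = "exhaustive")
    rI <- multiscan(fx$sites, fx$library, fx$pair, mode = "iterative")
    expect_gte(attr(rI, "objective"), attr(rE, "objective") - 1e-9)
    # trace moves must strictly decrease the objective
    tr <- attr(rI, "trace")
    if (nrow(tr) > 1) expect_true(all(diff(tr$objective) < 0))
  }
})

test_that("scan errors are informative", {
  fx <- make_scan_instance(301)
  orphan <- fx$sites[1, ]
  orphan$type <- "MISSING"
  expect_error(multiscan(orphan, fx$library, fx$pair),
               class = "catfield_empty_library")
  expect_error(multiscan(fx$sites, fx$library, fx$pair, cap = 10), "cap")
  expect_error(scan_objective(c("rot1"), fx$sites, fx$library, fx$pair),
               "one rotamer per site")
})

test_that("crystal-vs-scan reports plain per-site DTSS differences", {
  fx <- make_rotamer_library(51)
  res <- multiscan(fx$sites, fx$library, fx$pair, mode = "exhaustive")
  rep <- crystal_vs_scan_report(fx$sites, res, fx$pair, fx$library)
  for (i in seq_len(nrow(rep))) {
    d_scan <- dtss(place_rotamer(fx$sites[i, ], rep$rotamer_scan[i], fx$library),
                   fx$pair)
    d_cr <- dtss(place_rotamer(fx$sites[i, ], rep$rotamer_crystal[i], fx$library),
                 fx$pair)
    expect_equal(rep$dtss_scan[i], d_scan, tolerance = 1e-9)
    expect_equal(rep$delta[i], d_scan - d_cr, tolerance = 1e-9)
  }
  # scan choosing the crystal rotamer everywhere means all deltas vanish
  forced <- fx$sites
  forced$crystal_rotamer <- res$rotamer_id
  rep0 <- crystal_vs_scan_report(forced, res, fx$pair, fx$library)
  expect_true(all(abs(rep0$delta) < 1e-12))

  # missing crystal id: skipped with a warning
  partial <- fx$sites
  partial$crystal_rotamer[2] <- NA_character_
  expect_warning(rep1 <- crystal_vs_scan_report(partial, res, fx$pair, fx$library),
                 "skipped")
  expect_equal(nrow(rep1), nrow(fx$sites) - 1)
})
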