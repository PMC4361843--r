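test_that("largest-remainder apportionment reproduces printed compositions exactly", {
  expect_identical(
    apportion_counts(leaflet_composition(PC = 0.8, PS = 0.1, PIP2 = 0.1), 200),
    c(PC = 160L, PS = 20L, PIP2 = 20L))
  expect_identical(
    apportion_counts(leaflet_composition(PC = 0.10, PE = 0.40, PS = 0.15,
                                         PIP2 = 0.10, CHOL = 0.25), 200),
    c(PC = 20L, PE = 80L, PS = 30L, PIP2 = 20L, CHOL = 50L))
})

test_that("apportionment ties break by species name, verified by enumeration", {
  # brute-force oracle: all integer splits of n = 3 over two species; the
  # largest-remainder solution minimizes max |count - quota|, ties to the
  # lexicographically smaller species
  comp <- leaflet_composition(PC = 0.5, PS = 0.5)
  got <- apportion_counts(comp, 3)
  splits <- cbind(0:3, 3:0)
  err <- apply(splits, 1, function(s) max(abs(s - c(1.5, 1.5))))
  best <- splits[err == min(err), , drop = FALSE]
  expect_true(any(apply(best, 1, function(s) all(s == got))))
  expect_identical(got, c(PC = 2L, PS = 1L))  # tie goes to PC
  # counts always sum to n
  set.seed(3)
  for (i in 1:20) {
    f <- runif(3); f <- f / sum(f)
    cc <- apportion_counts(leaflet_composition(PC = f[1], PS = f[2],
                                               PIP2 = f[3]), 37)
    expect_identical(sum(cc), 37L)
  }
})

test_that("composition validation rejects bad fractions and unknown species", {
  expect_error(leaflet_composition(PC = 0.7, PS = 0.1), "sum to")
  expect_error(leaflet_composition(PC = 1.2, PS = -0.2), "negative")
  expect_error(leaflet_composition(XXX = 1), "unknown lipid species")
  expect_silent(leaflet_composition(PC = 0.5, PS = 0.5 - 1e-12, PIP2 = 1e-12))
})

test_that("build_leaflet places the right counts without hard-core overlap", {
  comp <- std_composition()
  lf <- build_leaflet(comp, 100, 80, seed = 4)
  expect_identical(lf$counts, c(PC = 80L, PS = 10L, PIP2 = 10L))
  expect_identical(length(lf$species), 100L)
  expect_true(all(lf$positions >= 0 & lf$positions < 80))
  # min-image pair distances all >= 2 * bead_radius
  d <- as.matrix(dist(lf$positions))
  for (k in 1:2) {
    dd <- abs(outer(lf$positions[, k], lf$positions[, k], "-"))
    dd <- pmin(dd, 80 - dd)
    if (k == 1) dx <- dd else dy <- dd
  }
  dmin <- sqrt(dx^2 + dy^2); diag(dmin) <- Inf
  expect_gte(min(dmin), 2 * lf$bead_radius - 1e-9)
  # too-dense packing errors out
  expect_error(build_leaflet(comp, 500, 30, seed = 1), "packing error")
})

test_that("protein placement follows the arm geometry", {
  m <- insr_like_model()
  anc <- place_protein(m, 160)
  expect_identical(nrow(anc), 21L)
  expect_identical(anc$label[1], "TM")
  expect_equal(anc$x[6] - anc$x[1], 5 * 3.5)  # residue 5 at 17.5 A
  expect_equal(unique(anc$y), 80)
  expect_identical(anc$charge[1], 0L)
  # empty JM: single TM anchor
  anc0 <- place_protein(tm_only_model(), 60)
  expect_identical(nrow(anc0), 1L)
  # arm exceeding half the box
  expect_error(place_protein(m, 100), "geometry error")
})

test_that("simulation is bit-reproducible under a fixed seed and conserves labels", {
  cfg <- small_config(seed = 9)
  m <- short_model()
  t1 <- simulate_replicates(m, std_composition(), cfg, 1L)[[1]]
  t2 <- simulate_replicates(m, std_composition(), cfg, 1L)[[1]]
  expect_identical(t1$coords, t2$coords)
  expect_identical(t1$species, t2$species)
  expect_true(all(t1$coords >= 0 & t1$coords < cfg$box_edge))
  expect_identical(dim(t1$coords), c(150L, 56L, 2L))
  # a different replicate id gives different noise
  t3 <- simulate_replicates(m, std_composition(),
                            small_config(seed = 10), 1L)[[1]]
  expect_false(identical(t1$coords, t3$coords))
})

test_that("with zero coupling the time-averaged density is uniform outside the footprint", {
  # TM-only anchor, epsilon_elec = 0; chi-square on a 3x3 grid of 20 A
  # cells, centre cell (protein footprint) excluded; frames saved at a
  # stride long enough to decorrelate bead positions at the cell scale
  cfg <- sim_config(box_edge = 60, n_lipids = 40, n_frames = 100,
                    save_stride = 16000, n_equil = 8000, epsilon_elec = 0,
                    seed = 31)
  tr <- simulate_replicates(tm_only_model(), std_composition(), cfg, 1L)[[1]]
  ix <- pmin(floor(tr$coords[, , 1] / 20) + 1L, 3L)
  iy <- pmin(floor(tr$coords[, , 2] / 20) + 1L, 3L)
  cell <- as.vector((ix - 1L) * 3L + iy)
  keep <- cell != 5L  # drop the centre cell holding the anchor
  counts <- tabulate(ifelse(cell[keep] > 5L, cell[keep] - 1L, cell[keep]),
                     nbins = 8L)
  p <- stats::chisq.test(counts, p = rep(1 / 8, 8))$p.value
  expect_gt(p, 0.01)
})

test_that("with zero coupling PIP2 and PC are indistinguishable around the protein", {
  cfg <- small_config(seed = 41, epsilon_elec = 0)
  trajs <- simulate_replicates(short_model(), std_composition(), cfg, 3L)
  rp <- lateral_rdf(trajs, "PIP2", r_max = 25)
  rc <- lateral_rdf(trajs, "PC", r_max = 25)
  v_p <- apply(rp$per_replicate, 2, first_shell_rdf_value, r = rp$r)
  v_c <- apply(rc$per_replicate, 2, first_shell_rdf_value, r = rc$r)
  pooled_sd <- sqrt((stats::var(v_p) + stats::var(v_c)) / 2)
  expect_lt(abs(mean(v_p) - mean(v_c)), 4 * pooled_sd + 0.02)
})

test_that("instability in the integrator is reported, not silently wrapped", {
  cfg <- small_config(seed = 5, timestep = 50)  # absurd timestep
  expect_error(
    simulate_replicates(short_model(4), std_composition(), cfg, 1L),
    "instability|smaller timestep")
})

test_that("calibration scan is monotone and honours its window contract", {
  m <- short_model(3)
  comp <- std_composition()
  cfg <- small_config(seed = 17)
  grid <- c(0, 6, 24)
  # window [0, Inf): smallest grid value wins
  eps <- calibrate_affinity(m, comp, cfg, grid = grid,
                            target_window = c(0, Inf), n_replicates = 1L)
  expect_identical(as.numeric(eps), 0)
  scan <- attr(eps, "scan")
  # mean first-shell count non-decreasing in epsilon (within noise)
  expect_true(all(diff(scan$mean_first_shell) > -0.3))
  # strong overall increase from excluded-volume-only to strong coupling
  expect_gt(scan$mean_first_shell[3], scan$mean_first_shell[1])
  # excluded-volume-only occupancy cannot reach the 4-6 window here
  expect_lt(scan$mean_first_shell[1], 4)
  expect_error(
    calibrate_affinity(m, comp, cfg, grid = 0, target_window = c(4, 6),
                       n_replicates = 1L),
    "calibration error")
})
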