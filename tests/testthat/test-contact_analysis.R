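test_that("contact counting matches a brute-force all-pairs oracle", {
  for (seed in c(1, 2, 3)) {
    tr <- random_toy(seed)
    for (sp in c("PIP2", "PS", "PC")) {
      cm <- count_contacts(tr, sp)
      expect_identical(cm$counts, oracle_contacts(tr, sp))
    }
  }
})

test_that("contact cutoff boundary is inclusive at exactly 6 A", {
  anc <- toy_anchors(cbind(c(10, 13, 16), c(10, 10, 10)))
  coords <- array(0, dim = c(1, 2, 2))
  coords[1, 1, ] <- c(13, 10 + 6.0)    # exactly 6.0 from residue JM1
  coords[1, 2, ] <- c(10, 10 + 6.01)   # just outside for the TM anchor
  tr <- toy_trajectory(coords, c("PIP2", "PIP2"), anc, 40)
  cm <- count_contacts(tr, "PIP2")
  expect_identical(cm$counts[, 1], c(TM = 0L, JM1 = 1L, JM2 = 0L))
})

test_that("a single nearby bead is credited to the right residue only", {
  anc <- toy_anchors(cbind(c(10, 14, 18, 22), c(10, 10, 10, 10)))
  coords <- array(0, dim = c(2, 3, 2))
  coords[, 1, 1] <- 18; coords[, 1, 2] <- 15   # 5.0 A from JM2, others > 6
  coords[, 2, 1] <- 35; coords[, 2, 2] <- 35
  coords[, 3, 1] <- 2;  coords[, 3, 2] <- 30
  tr <- toy_trajectory(coords, rep("PIP2", 3), anc, 40)
  cm <- count_contacts(tr, "PIP2")
  expect_identical(cm$counts[, 1],
                   c(TM = 0L, JM1 = 0L, JM2 = 1L, JM3 = 0L))
  expect_error(count_contacts(tr, "GM3"), "unknown species")
})

test_that("mean contacts averages frames equally across replicates", {
  cm <- make_cm(matrix(c(1, 0, 1), 1))
  expect_equal(unname(mean_contacts(cm)), 2 / 3)
  cm0 <- make_cm(matrix(0L, 2, 5))
  expect_equal(unname(mean_contacts(cm0)), c(0, 0))
  cmr <- make_cm(matrix(c(1, 1, 0, 0), 1), rep_frames = c(2L, 2L))
  expect_equal(unname(mean_contacts(cmr)), 0.5)
  expect_error(mean_contacts(make_cm(matrix(integer(0), 1, 0))), "empty")
})

test_that("occupancy fraction is a percentage ignoring multiplicity", {
  expect_equal(unname(occupancy_fraction(make_cm(matrix(c(1, 1, 0, 1, 0), 1)))), 60)
  expect_equal(unname(occupancy_fraction(make_cm(matrix(c(2, 3, 5), 1)))), 100)
  expect_equal(unname(occupancy_fraction(make_cm(matrix(0L, 1, 4)))), 0)
})

test_that("residence time is occupancy time over association events", {
  rt <- residence_time(make_cm(matrix(c(1, 1, 0, 1, 0), 1), frame_interval = 2))
  expect_equal(as.numeric(rt), 3 * 2 / 2)  # occupancy 3 frames, 2 events
  expect_equal(as.numeric(residence_time(make_cm(matrix(c(1, 1, 1, 1), 1),
                                             frame_interval = 0.5))), 2)
  rt0 <- residence_time(make_cm(matrix(0L, 1, 5)))
  expect_equal(as.numeric(rt0), 0)
  expect_true(attr(rt0, "no_events")[[1]])
})

test_that("events never bridge replicate boundaries", {
  # occupied run spanning the replicate seam counts as two events
  cm <- make_cm(matrix(c(1, 1, 1, 1), 1), rep_frames = c(2L, 2L))
  rt <- residence_time(cm)
  expect_identical(unname(attr(rt, "events")), 2L)
  expect_equal(as.numeric(rt), 4 / 2)
  # occupancy 100% in a single replicate => one event spanning all frames
  cm1 <- make_cm(matrix(1L, 1, 6), frame_interval = 3)
  expect_equal(unname(occupancy_fraction(cm1)), 100)
  expect_identical(unname(attr(residence_time(cm1), "events")), 1L)
  expect_equal(as.numeric(residence_time(cm1)), 18)  # the whole simulated time
})

test_that("gap tolerance merges short vacancies into one event", {
  counts <- matrix(c(1, 0, 1, 1, 0, 0, 1), 1)
  expect_identical(unname(attr(residence_time(make_cm(counts)), "events")), 3L)
  cm_gap <- make_cm(counts, gap_tolerance = 1L)
  expect_identical(unname(attr(residence_time(cm_gap), "events")), 2L)
})

test_that("summed mean contacts equal the per-frame mean of total contact pairs", {
  tr <- random_toy(7)
  cm <- count_contacts(tr, "PS")
  direct <- mean(colSums(oracle_contacts(tr, "PS")))
  expect_equal(sum(mean_contacts(cm)), direct)
})

test_that("first-shell count matches hand-built geometries", {
  anc <- toy_anchors(cbind(c(10, 14), c(10, 10)))
  coords <- array(0, dim = c(3, 2, 2))
  coords[, 1, 1] <- 14; coords[, 1, 2] <- 14    # 4 A from JM1 every frame
  coords[, 2, 1] <- 30; coords[, 2, 2] <- 30    # always far
  tr <- toy_trajectory(coords, c("PIP2", "PIP2"), anc, 40)
  expect_equal(first_shell_count(tr, "PIP2"), 1)
  tr2 <- toy_trajectory(coords[, 2, , drop = FALSE], "PIP2",
                        anc, 40)
  expect_equal(first_shell_count(tr2, "PIP2"), 0)
})

test_that("contact summary is tidy and internally consistent", {
  tr <- random_toy(12)
  cm <- count_contacts(tr, "PC")
  summ <- contact_summary(cm, "toy")
  expect_identical(sort(unique(summ$statistic)),
                   sort(c("mean_contacts", "occupancy_pct", "residence_time")))
  expect_identical(nrow(summ), 3L * nrow(cm$counts))
  mc <- summ$value[summ$statistic == "mean_contacts"]
  expect_equal(mc, unname(mean_contacts(cm)))
})
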