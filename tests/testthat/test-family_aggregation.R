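test_that("positional mean contacts average receptors elementwise", {
  expect_equal(positional_mean_contacts(list(c(1, 0), c(3, 2))), c(2, 1))
  one <- runif(20)
  expect_equal(positional_mean_contacts(rep(list(one), 58)), one)
  # definition check: mean equals sum/N
  set.seed(2)
  profs <- replicate(58, runif(20), simplify = FALSE)
  expect_equal(positional_mean_contacts(profs),
               Reduce(`+`, profs) / 58)
  expect_error(positional_mean_contacts(list(c(1, 2), c(1, 2, 3))), "shape")
  expect_error(positional_mean_contacts(list()), "empty")
})

test_that("aggregation is permutation-invariant over receptors", {
  set.seed(14)
  profs <- replicate(9, runif(20), simplify = FALSE)
  expect_equal(positional_mean_contacts(profs),
               positional_mean_contacts(profs[sample(9)]))
})

test_that("positional residue probabilities sum to 1 and respect the classes", {
  seqs <- c("KASL", "KDSL", "KRSP")
  pr <- positional_residue_probability(seqs)
  expect_equal(colSums(pr$class_prob), rep(1, 4), ignore_attr = TRUE)
  expect_equal(colSums(pr$aa_freq), rep(1, 4), ignore_attr = TRUE)
  expect_equal(pr$class_prob["basic", 1], 1)      # all K at position 1
  expect_equal(pr$class_prob["basic", 3], 0)      # no R/K at position 3
  expect_equal(pr$aa_freq["K", 1], 1)
  expect_equal(pr$class_prob["acidic", 2], 1 / 3)
  expect_error(positional_residue_probability(c("KA", "KAL")), "shape")
})

test_that("clustering propensity follows its literal definition", {
  # 1 of 5 PIP2 beads inside the shell in every frame, species at 10%
  anc <- toy_anchors(cbind(20, 20), labels = "TM")
  coords <- array(35, dim = c(4, 10, 2))
  coords[, 1, ] <- 22          # within 6 A of the anchor
  species <- c(rep("PIP2", 5), rep("PC", 5))
  tr <- toy_trajectory(coords, species, anc, 60)
  comp <- leaflet_composition(PC = 0.9, PIP2 = 0.1)
  # mean within-shell fraction 1/5 = 0.2, divided by 0.1 -> 2.0
  expect_equal(clustering_propensity(tr, "PIP2", comp), 2)
  expect_error(clustering_propensity(tr, "PS", comp), "absent")
})

test_that("uniform non-interacting species matches the geometric shell value", {
  # C_uniform = (accessible shell area / box area) / leaflet fraction,
  # computed by direct geometric integration on a fine grid
  set.seed(21)
  box <- 100; n <- 2000; nf <- 40
  coords <- array(runif(nf * n * 2, 0, box), dim = c(nf, n, 2))
  anc <- toy_anchors(cbind(c(50, 53.5, 57), rep(50, 3)))
  tr <- toy_trajectory(coords, rep("PC", n), anc, box)
  comp <- leaflet_composition(PC = 1)
  gx <- seq(0.05, box - 0.05, by = 0.1)
  inside <- 0
  dy2 <- outer(anc$y, gx, "-")^2          # anchors x grid-y
  for (x in gx) {
    d <- sqrt((anc$x - x)^2 + dy2)        # recycles per anchor row
    inside <- inside + sum(apply(d, 2, min) <= 6)
  }
  shell_frac <- inside / (length(gx)^2)
  C <- clustering_propensity(tr, "PC", comp)
  expect_equal(C, shell_frac, tolerance = 0.05)
})

test_that("charge-propensity correlation handles linear, degenerate and sparse cases", {
  rec <- data.frame(receptor_id = letters[1:5], species = "PIP2",
                    propensity = c(1, 2, 3, 4, 5),
                    net_jm_charge = 1:5)
  r <- charge_propensity_correlation(rec, "PIP2")
  expect_equal(as.numeric(r), 1)
  expect_identical(attr(r, "n"), 5L)
  # negative charges are excluded by default
  rec2 <- rbind(rec, data.frame(receptor_id = "f", species = "PIP2",
                                propensity = 99, net_jm_charge = -2))
  expect_equal(as.numeric(charge_propensity_correlation(rec2, "PIP2")), 1)
  expect_identical(attr(charge_propensity_correlation(
    rec2, "PIP2", positive_only = FALSE), "n"), 6L)
  # constant propensity is flagged degenerate
  rec3 <- transform(rec, propensity = 2)
  r3 <- charge_propensity_correlation(rec3, "PIP2")
  expect_true(is.nan(as.numeric(r3)))
  expect_true(attr(r3, "degenerate"))
  expect_error(charge_propensity_correlation(rec[1:2, ], "PIP2"),
               "insufficient data")
  # spearman option
  expect_equal(as.numeric(charge_propensity_correlation(
    rec, "PIP2", method = "spearman")), 1)
})

test_that("manifest lists the 58 receptors and JM extraction yields 20 residues", {
  ids <- rtk_manifest()
  expect_length(ids, 58L)
  expect_identical(anyDuplicated(ids), 0L)
  expect_true(all(c("EGFR", "INSR", "EPHA2", "ALK") %in% ids))
  expect_identical(nchar(insr_like_model()$jm_sequence), 20L)
})
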