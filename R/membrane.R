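#' Build a leaflet: species assignment and non-overlapping initial positions
#'
#' Apportions `n_lipids` among the species of `composition` by largest
#' remainder, then draws initial headgroup-bead positions uniformly in the
#' periodic box by rejection sampling with a hard-core minimum pair
#' distance of `2 * bead_radius`. Positions optionally also keep clear of a
#' set of fixed `exclude` points (protein anchors) at the same distance.
#'
#' @param composition A `leaflet_composition` (fractions summing to 1).
#' @param n_lipids Total lipid count.
#' @param box_edge Edge length of the square periodic box (A).
#' @param seed Integer seed for the placement RNG.
#' @param exclude Optional matrix (k x 2) of fixed positions to keep clear
#'   of (e.g. protein anchors).
#' @param bead_radius Hard-core bead radius (A, default 2.35).
#' @return Object of class `jm_leaflet`: list with `species` (character,
#'   length n_lipids, sorted by species block), `positions` (n x 2 matrix),
#'   `counts`, `composition`, `box_edge`, `bead_radius`, `seed`.
#' @export
build_leaflet <- function(composition, n_lipids, box_edge, seed,
                          exclude = NULL, bead_radius = 2.35) {
  if (!inherits(composition, "leaflet_composition"))
    composition <- leaflet_composition(composition)
  n_lipids <- as.integer(n_lipids)
  box_edge <- as.numeric(box_edge)
  stopifnot(n_lipids > 0L, box_edge > 0)
  counts <- apportion_counts(composition, n_lipids)
  # feasibility: disc packing beyond ~55% area fraction will not place
  area_frac <- n_lipids * pi * bead_radius^2 / box_edge^2
  if (area_frac > 0.55)
    stop("packing error: area fraction ", format(round(area_frac, 3)),
         " too high to place ", n_lipids, " lipids in a ", box_edge,
         " A box", call. = FALSE)
  dmin2 <- (2 * bead_radius)^2
  pos <- matrix(NA_real_, n_lipids, 2)
  exc <- if (is.null(exclude)) matrix(numeric(0), 0, 2) else
    matrix(as.numeric(exclude), ncol = 2)
  set.seed(as.integer(seed))
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * n_lipids
  while (placed < n_lipids) {
    if (attempts >= max_attempts)
      stop("packing error: rejection sampling failed after ", attempts,
           " attempts", call. = FALSE)
    p <- stats::runif(2, 0, box_edge)
    attempts <- attempts + 1L
    ok <- TRUE
    if (placed > 0L) {
      d2 <- .min_image_dist2(pos[seq_len(placed), , drop = FALSE], p, box_edge)
      if (any(d2 < dmin2)) ok <- FALSE
    }
    if (ok && nrow(exc)) {
      d2 <- .min_image_dist2(exc, p, box_edge)
      if (any(d2 < dmin2)) ok <- FALSE
    }
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- p
    }
  }
  species <- rep(names(counts), counts)
  structure(list(
    species = species,
    positions = pos,
    counts = counts,
    composition = composition,
    box_edge = box_edge,
    bead_radius = bead_radius,
    seed = as.integer(seed)
  ), class = "jm_leaflet")
}

# squared min-image distances from each row of `mat` to point `p`
.min_image_dist2 <- function(mat, p, box) {
  dx <- abs(mat[, 1] - p[1]); dx <- pmin(dx, box - dx)
  dy <- abs(mat[, 2] - p[2]); dy <- pmin(dy, box - dy)
  dx * dx + dy * dy
}

#' Place the TM-JM protein footprint in the leaflet plane
#'
#' One immobile TM anchor bead at the box centre; JM residue i at distance
#' `i * spacing` from the TM anchor along +x, encoding the surface-lying
#' pose of the JM arm. Anchors never move during simulation.
#'
#' @param model A `tmjm_model` (its `jm_sequence` supplies residues).
#' @param box_edge Box edge length (A).
#' @param spacing Inter-anchor spacing along the arm (A, default 3.5).
#' @return Data frame of anchors: `label` ("TM", "JM1", ...), `residue`
#'   (NA for the TM bead), `class`, `charge`, `x`, `y`.
#' @export
place_protein <- function(model, box_edge, spacing = 3.5) {
  stopifnot(inherits(model, "tmjm_model"), box_edge > 0, spacing > 0)
  aa <- strsplit(model$jm_sequence, "", fixed = TRUE)[[1]]
  n_jm <- length(aa)
  if (n_jm * spacing >= box_edge / 2)
    stop("geometry error: JM arm (", n_jm * spacing,
         " A) exceeds half the box edge (", box_edge / 2, " A)",
         call. = FALSE)
  cx <- box_edge / 2
  data.frame(
    label = c("TM", if (n_jm) paste0("JM", seq_len(n_jm))),
    residue = c(NA_character_, aa),
    class = c(NA_character_, if (n_jm) classify_residue(aa)),
    charge = c(0L, if (n_jm) residue_charge(aa)),
    x = cx + c(0, seq_len(n_jm) * spacing),
    y = rep(cx, n_jm + 1L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for the membrane emulator
#'
#' Defaults define the package's standard desk-scale study conditions:
#' a 160 A periodic box with 400 headgroup beads (~64 A^2 per lipid),
#' uniform diffusion coefficient 1 A^2/tau, timestep 0.005 tau, 2x10^4
#' equilibration steps, 600 saved frames at stride 100 (300 tau of
#' production), Debye length 7.8 A (0.15 M NaCl) and the calibrated
#' electrostatic coupling returned by [default_epsilon_elec()].
#'
#' @param box_edge Box edge (A).
#' @param n_lipids Lipid count.
#' @param timestep Integration timestep (tau).
#' @param n_frames Number of saved frames.
#' @param save_stride Steps between saved frames.
#' @param n_equil Equilibration steps discarded before saving.
#' @param kT Thermal energy (energy unit; 1 by convention).
#' @param debye_length Electrostatic screening length (A).
#' @param epsilon_elec Electrostatic coupling strength (kT.A).
#' @param bead_radius Hard-core bead radius (A).
#' @param diffusion Lateral diffusion coefficient (A^2/tau).
#' @param wca_epsilon Excluded-volume (WCA) energy scale (kT).
#' @param seed Base integer seed; replicate r uses `seed + r`.
#' @return Object of class `sim_config` (list of the above).
#' @export
sim_config <- function(box_edge = 160, n_lipids = 400, timestep = 0.005,
                       n_frames = 600, save_stride = 100, n_equil = 20000,
                       kT = 1, debye_length = 7.8,
                       epsilon_elec = default_epsilon_elec(),
                       bead_radius = 2.35, diffusion = 1, wca_epsilon = 1,
                       seed = 1L) {
  cfg <- list(box_edge = box_edge, n_lipids = n_lipids, timestep = timestep,
              n_frames = n_frames, save_stride = save_stride,
              n_equil = n_equil, kT = kT, debye_length = debye_length,
              epsilon_elec = epsilon_elec, bead_radius = bead_radius,
              diffusion = diffusion, wca_epsilon = wca_epsilon,
              seed = as.integer(seed))
  num <- c("box_edge", "n_lipids", "timestep", "n_frames", "save_stride",
           "kT", "debye_length", "bead_radius", "diffusion", "wca_epsilon")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("sim_config: ", f, " must be a positive scalar", call. = FALSE)
  if (cfg$n_equil < 0 || cfg$epsilon_elec < 0)
    stop("sim_config: n_equil and epsilon_elec must be non-negative",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Calibrated default electrostatic coupling strength
#'
#' The one free parameter of the emulator, fixed once by
#' [calibrate_affinity()] so that the synthetic INSR-like system in the
#' 80:10:10 PC:PS:PIP2 leaflet reproduces a first-interaction-shell PIP2
#' count in the 4-6 window; the calibration scan is shipped at
#' `inst/extdata/calibration_log.csv`.
#'
#' @return Numeric scalar (kT.A).
#' @export
default_epsilon_elec <- function() 16

#' Run the Brownian-dynamics membrane emulator
#'
#' Overdamped Langevin dynamics of lipid headgroup beads in a 2D periodic
#' box around a fixed protein anchor set. Per step, each lipid moves by
#' `-(D/kT) grad(U) dt + sqrt(2 D dt) eta` with standard-normal `eta` per
#' component. `U` sums WCA excluded-volume terms over lipid-lipid and
#' lipid-anchor pairs and screened-Coulomb (Yukawa) terms
#' `eps_elec * q_res * q_lip * exp(-r/lambda_D) / r` over charged
#' anchor-lipid pairs. Identical seed gives a bit-identical trajectory.
#'
#' @param anchors Anchor data frame from [place_protein()].
#' @param leaflet A `jm_leaflet` from [build_leaflet()].
#' @param config A `sim_config`; its `seed` (plus `replicate_id`) seeds the
#'   noise.
#' @param replicate_id Integer replicate index (default 1); the RNG is
#'   seeded with `config$seed + replicate_id`.
#' @return Object of class `jm_trajectory`: `coords` array
#'   (frames x lipids x 2), `species`, `anchors`, `box_edge`,
#'   `frame_interval`, `seed`, `replicate_id`.
#' @export
simulate_membrane <- function(anchors, leaflet, config, replicate_id = 1L) {
  stopifnot(inherits(leaflet, "jm_leaflet"), inherits(config, "sim_config"))
  if (!is.data.frame(anchors) || !all(c("x", "y", "charge") %in% names(anchors)))
    stop("anchors must be a data frame from place_protein()", call. = FALSE)
  if (leaflet$box_edge != config$box_edge)
    stop("leaflet and config disagree on box_edge", call. = FALSE)
  if (any(anchors$x < 0 | anchors$x >= config$box_edge |
          anchors$y < 0 | anchors$y >= config$box_edge))
    stop("anchors outside the box", call. = FALSE)
  qlip <- lipid_species(leaflet$species)$charge
  seed <- config$seed + as.integer(replicate_id)
  set.seed(seed)
  res <- sim_core(
    pos0 = leaflet$positions,
    lipid_charge = as.numeric(qlip),
    anchor_pos = cbind(anchors$x, anchors$y),
    anchor_charge = as.numeric(anchors$charge),
    box = config$box_edge,
    dt = config$timestep,
    n_equil = as.integer(config$n_equil),
    n_steps = as.integer(config$n_frames * config$save_stride),
    stride = as.integer(config$save_stride),
    D = config$diffusion,
    kT = config$kT,
    sigma = 2 * config$bead_radius,
    eps_wca = config$wca_epsilon,
    eps_elec = config$epsilon_elec,
    lambda = config$debye_length
  )
  coords <- array(res$frames,
                  dim = c(config$n_frames, nrow(leaflet$positions), 2))
  structure(list(
    coords = coords,
    species = leaflet$species,
    anchors = anchors,
    box_edge = config$box_edge,
    frame_interval = config$timestep * config$save_stride,
    seed = seed,
    replicate_id = as.integer(replicate_id)
  ), class = "jm_trajectory")
}

#' @export
print.jm_trajectory <- function(x, ...) {
  cat("Synthetic membrane trajectory: ", dim(x$coords)[1], " frames, ",
      dim(x$coords)[2], " lipids (",
      paste(sprintf("%s %d", names(table(x$species)), table(x$species)),
            collapse = ", "),
      "), ", nrow(x$anchors), " anchors\n", sep = "")
  cat("  box ", x$box_edge, " A, frame interval ", x$frame_interval,
      " tau, seed ", x$seed, ", replicate ", x$replicate_id, "\n", sep = "")
  invisible(x)
}

#' Simulate seeded replicates of one system
#'
#' Runs [simulate_membrane()] `n_replicates` times; replicate r draws its
#' initial lipid placement with seed `config$seed + r` and its dynamics
#' noise with the same seed, mirroring repeat simulations with different
#' initial lipid positions and velocity seeds.
#'
#' @param model A `tmjm_model`.
#' @param composition A `leaflet_composition`.
#' @param config A `sim_config`.
#' @param n_replicates Number of replicates (default 3).
#' @return List of `jm_trajectory` objects.
#' @export
simulate_replicates <- function(model, composition, config,
                                n_replicates = 3L) {
  anchors <- place_protein(model, config$box_edge)
  lapply(seq_len(n_replicates), function(r) {
    leaflet <- build_leaflet(composition, config$n_lipids, config$box_edge,
                             seed = config$seed + r,
                             exclude = cbind(anchors$x, anchors$y),
                             bead_radius = config$bead_radius)
    simulate_membrane(anchors, leaflet, config, replicate_id = r)
  })
}

#' Calibrate the electrostatic coupling against a first-shell window
#'
#' Scans `epsilon_elec` over a geometric grid, runs short replicate
#' simulations at each value, and returns the smallest grid value whose
#' mean first-interaction-shell count of the target species falls inside
#' `target_window`. The full scan is returned as an attribute for logging.
#'
#' @param model A `tmjm_model` defining the anchor layout.
#' @param composition A `leaflet_composition`.
#' @param config A `sim_config`; its `epsilon_elec` is overridden by the
#'   grid values.
#' @param grid Numeric vector of coupling strengths to scan (ascending).
#' @param target_window Length-2 numeric window for the mean first-shell
#'   count (default `c(4, 6)`).
#' @param species Species whose first-shell count is calibrated
#'   (default "PIP2").
#' @param cutoff First-shell cutoff (A, default 6).
#' @param n_replicates Replicates per grid point (default 2).
#' @return The selected `epsilon_elec` (numeric scalar) with attribute
#'   `"scan"` — a data frame of grid values and measured mean counts.
#' @export
calibrate_affinity <- function(model, composition, config,
                               grid = c(2, 4, 8, 12, 16, 24, 32, 48),
                               target_window = c(4, 6), species = "PIP2",
                               cutoff = 6, n_replicates = 2L) {
  stopifnot(length(target_window) == 2L, target_window[1] <= target_window[2])
  grid <- sort(as.numeric(grid))
  means <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cfg <- config
    cfg$epsilon_elec <- grid[i]
    trajs <- simulate_replicates(model, composition, cfg, n_replicates)
    means[i] <- first_shell_count(trajs, species, cutoff)
  }
  scan <- data.frame(epsilon_elec = grid, mean_first_shell = means)
  hit <- which(means >= target_window[1] & means <= target_window[2])
  if (!length(hit)) {
    stop("calibration error: no scanned epsilon_elec in [",
         paste(grid[c(1, length(grid))], collapse = ", "),
         "] gives a mean first-shell ", species, " count in [",
         target_window[1], ", ", target_window[2], "] (measured range ",
         paste(format(round(range(means), 2)), collapse = " - "), ")",
         call. = FALSE)
  }
  structure(grid[hit[1]], scan = scan)
}
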