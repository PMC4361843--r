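# Shared fixtures: hand-built trajectories/contact matrices and cached
# simulation runs (computed once per test session, reused across tests).

.sim_cache <- new.env(parent = emptyenv())

std_composition <- function() leaflet_composition(PC = 0.8, PS = 0.1, PIP2 = 0.1)

# full default-scale calibrated INSR-like run, 3 replicates
calibrated_run <- function() {
  if (is.null(.sim_cache$run)) {
    cfg <- sim_config(seed = 20L)
    .sim_cache$run <- simulate_replicates(insr_like_model(),
                                          std_composition(), cfg, 3L)
  }
  .sim_cache$run
}

# reduced-length config for comparative tests (same geometry/physics as the
# default, fewer frames)
fast_config <- function(seed, n_frames = 300, ...) {
  sim_config(n_frames = n_frames, n_equil = 10000, seed = seed, ...)
}

# small neutral test system: short JM (or none) in a small box
small_config <- function(seed, ...) {
  sim_config(box_edge = 60, n_lipids = 56, n_frames = 150, n_equil = 4000,
             seed = seed, ...)
}

# a short-JM model that fits the small box (arm 5 x 3.5 = 17.5 A < 30 A)
short_model <- function(n_basic = 2L) synthetic_tmjm(n_basic, jm_length = 5L)

tm_only_model <- function() synthetic_tmjm(0L, jm_length = 0L)

# hand-built trajectory with arbitrary coordinates (no dynamics)
toy_trajectory <- function(coords, species, anchors, box_edge,
                           frame_interval = 1, seed = 0L, replicate_id = 1L) {
  structure(list(coords = coords, species = species, anchors = anchors,
                 box_edge = box_edge, frame_interval = frame_interval,
                 seed = as.integer(seed), replicate_id = as.integer(replicate_id)),
            class = "jm_trajectory")
}

toy_anchors <- function(xy, labels = NULL, charges = NULL) {
  n <- nrow(xy)
  data.frame(label = labels %||% c("TM", if (n > 1) paste0("JM", seq_len(n - 1))),
             residue = NA_character_, class = NA_character_,
             charge = charges %||% rep(0L, n),
             x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random toy system for oracle comparisons
random_toy <- function(seed, n_frames = 10L, n_lipids = 30L, box = 40) {
  set.seed(seed)
  coords <- array(runif(n_frames * n_lipids * 2, 0, box),
                  dim = c(n_frames, n_lipids, 2))
  species <- sample(c("PIP2", "PS", "PC"), n_lipids, replace = TRUE,
                    prob = c(0.3, 0.3, 0.4))
  anc <- toy_anchors(cbind(c(20, 23, 26), c(20, 20, 20)))
  toy_trajectory(coords, species, anc, box)
}

# hand-built contact matrix
make_cm <- function(counts, frame_interval = 1, rep_frames = ncol(counts),
                    species = "PIP2", gap_tolerance = 0L) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("JM", seq_len(nrow(counts)))
  anchors <- data.frame(label = rownames(counts), residue = NA_character_,
                        class = NA_character_, charge = 0L,
                        x = 0, y = 0, stringsAsFactors = FALSE)
  structure(list(counts = counts, species = species, cutoff = 6,
                 gap_tolerance = as.integer(gap_tolerance),
                 frame_interval = frame_interval,
                 rep_frames = rep_frames,
                 replicate_ids = seq_along(rep_frames), anchors = anchors),
            class = "contact_matrix")
}

# brute-force O(N^2) contact oracle, independent of count_contacts()
oracle_contacts <- function(tr, species, cutoff = 6) {
  sel <- which(tr$species == species)
  nf <- dim(tr$coords)[1]
  na <- nrow(tr$anchors)
  out <- matrix(0L, na, nf)
  for (f in seq_len(nf)) {
    for (a in seq_len(na)) {
      cnt <- 0L
      for (b in sel) {
        dx <- abs(tr$coords[f, b, 1] - tr$anchors$x[a])
        dx <- min(dx, tr$box_edge - dx)
        dy <- abs(tr$coords[f, b, 2] - tr$anchors$y[a])
        dy <- min(dy, tr$box_edge - dy)
        if (sqrt(dx^2 + dy^2) <= cutoff) cnt <- cnt + 1L
      }
      out[a, f] <- cnt
    }
  }
  rownames(out) <- tr$anchors$label
  out
}

# first-shell RDF statistic used for species-preference comparisons:
# maximum of the unit-area profile within the contact region (r <= 8 A)
first_shell_rdf_value <- function(profile_column, r) {
  max(profile_column[r <= 8])
}
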