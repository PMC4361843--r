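# min distance from each bead of `species` to the anchor set, all frames
.min_anchor_dist <- function(tr, species) {
  sel <- which(tr$species == species)
  anc <- cbind(tr$anchors$x, tr$anchors$y)
  nf <- dim(tr$coords)[1]
  unlist(lapply(seq_len(nf), function(f) {
    beads <- tr$coords[f, sel, , drop = FALSE]
    dim(beads) <- c(length(sel), 2L)
    d <- .mi_dist(anc, beads, tr$box_edge)
    apply(d, 2L, min)
  }))
}

#' Lateral radial distribution function, normalized to unit area
#'
#' For every frame and every bead of `species`, takes the minimum-image
#' distance to the whole protein anchor set, histograms the distances over
#' `[0, r_max]`, divides each bin by its annulus area (2D geometric
#' normalization), and rescales the profile so the area under the curve is
#' exactly 1, enabling comparison across species. With a list of
#' replicates, each replicate is normalized separately and the profile
#' reports their mean and standard deviation.
#'
#' @param traj A `jm_trajectory` or list of replicates.
#' @param species Lipid species name.
#' @param bin_width Bin width (A, default 1).
#' @param r_max Histogram range (A, default 30); must not exceed half the
#'   box edge.
#' @return Object of class `rdf_profile`: `breaks`, `r` (bin centres),
#'   `value` (replicate-mean unit-area profile), `sd`, `per_replicate`
#'   matrix, `species`, `bin_width`, `r_max`.
#' @export
lateral_rdf <- function(traj, species, bin_width = 1, r_max = 30) {
  trs <- .as_traj_list(traj)
  .check_species(trs, species)
  stopifnot(bin_width > 0, r_max > bin_width)
  box <- trs[[1]]$box_edge
  if (r_max > box / 2)
    stop("geometry error: r_max (", r_max, " A) exceeds half the box edge (",
         box / 2, " A)", call. = FALSE)
  breaks <- seq(0, r_max, by = bin_width)
  if (abs(breaks[length(breaks)] - r_max) > 1e-9)
    breaks <- c(breaks, r_max)
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  annulus <- pi * (breaks[-1]^2 - breaks[-length(breaks)]^2)
  widths <- diff(breaks)
  prof <- vapply(trs, function(tr) {
    d <- .min_anchor_dist(tr, species)
    d <- d[d <= r_max]
    if (!length(d))
      stop("no '", species, "' beads within r_max; cannot normalize RDF",
           call. = FALSE)
    h <- graphics::hist(d, breaks = breaks, plot = FALSE, right = TRUE)
    g <- h$counts / annulus          # geometric (annulus-area) normalization
    g / sum(g * widths)              # rescale to unit area under the curve
  }, numeric(length(centres)))
  prof <- matrix(prof, nrow = length(centres))
  structure(list(
    breaks = breaks,
    r = centres,
    value = rowMeans(prof),
    sd = if (ncol(prof) > 1L) apply(prof, 1L, stats::sd) else
      rep(NA_real_, length(centres)),
    per_replicate = prof,
    species = species,
    bin_width = bin_width,
    r_max = r_max
  ), class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat("Unit-area RDF: species ", x$species, ", ", length(x$r), " bins of ",
      x$bin_width, " A up to ", x$r_max, " A (", ncol(x$per_replicate),
      " replicate(s))\n", sep = "")
  pk <- first_peak(x)
  if (!is.na(pk)) cat("  first peak at ", pk, " A\n", sep = "")
  invisible(x)
}

#' Radial position of the first RDF peak
#'
#' Returns the centre of the first bin whose value strictly exceeds both
#' neighbours; the first bin qualifies if it strictly exceeds its right
#' neighbour. Ties resolve to the smaller radius by the first-match rule.
#' `NA` signals that no peak exists (monotonically flat/increasing tail
#' profiles).
#'
#' @param rdf An `rdf_profile`, or a numeric vector of bin values (then
#'   `r` supplies the bin centres).
#' @param r Bin centres when `rdf` is a plain vector.
#' @return Bin-centre radius of the first peak (A), or `NA` if none.
#' @export
first_peak <- function(rdf, r = NULL) {
  if (inherits(rdf, "rdf_profile")) {
    v <- rdf$value
    r <- rdf$r
  } else {
    v <- as.numeric(rdf)
    if (is.null(r)) r <- seq_along(v) - 0.5
  }
  n <- length(v)
  if (n < 3L) stop("first_peak needs at least 3 bins", call. = FALSE)
  if (v[1] > v[2]) return(r[1])
  for (i in 2:(n - 1L))
    if (v[i] > v[i - 1L] && v[i] > v[i + 1L]) return(r[i])
  NA_real_
}

#' Occupancy density map of a lipid species
#'
#' Divides the box into square cells and reports, per cell, the fraction
#' of frames (over all concatenated replicates) in which at least one bead
#' of the species lies in the cell — the 2D analogue of a VolMap-style
#' occupancy surface.
#'
#' @param traj A `jm_trajectory` or list of replicates.
#' @param species Lipid species name.
#' @param cell Cell edge (A, default 1).
#' @return Object of class `density_map`: `occupancy` matrix (x-cells x
#'   y-cells, values in [0, 1]), `cell`, `box_edge`, `species`, `n_frames`.
#' @export
density_map <- function(traj, species, cell = 1) {
  trs <- .as_traj_list(traj)
  .check_species(trs, species)
  stopifnot(cell > 0)
  box <- trs[[1]]$box_edge
  ncell <- ceiling(box / cell - 1e-9)
  acc <- matrix(0L, ncell, ncell)
  total <- 0L
  for (tr in trs) {
    sel <- which(tr$species == species)
    nf <- dim(tr$coords)[1]
    total <- total + nf
    for (f in seq_len(nf)) {
      ix <- pmin(floor(tr$coords[f, sel, 1] / cell) + 1L, ncell)
      iy <- pmin(floor(tr$coords[f, sel, 2] / cell) + 1L, ncell)
      hit <- unique(cbind(ix, iy))
      acc[hit] <- acc[hit] + 1L
    }
  }
  structure(list(
    occupancy = acc / total,
    cell = cell,
    box_edge = box,
    species = species,
    n_frames = total
  ), class = "density_map")
}

#' Per-label root-mean-square fluctuation
#'
#' RMSF of each tracked particle about its time-mean position; no
#' superposition or alignment is applied (protein anchors are fixed by
#' construction, and alignment of ingested tracks is the adapter's
#' responsibility).
#'
#' @param track Numeric array `[frames, labels, 2]` of positions, or a
#'   matrix `[frames, 2]` for a single track.
#' @param labels Optional label names (defaults to array dimnames or
#'   indices).
#' @return Named numeric vector of RMSF values.
#' @export
rmsf <- function(track, labels = NULL) {
  if (is.matrix(track)) {
    track <- array(track, dim = c(nrow(track), 1L, ncol(track)))
  }
  stopifnot(length(dim(track)) == 3L, dim(track)[3] == 2L)
  if (dim(track)[1] < 2L)
    stop("rmsf needs at least 2 frames", call. = FALSE)
  n_lab <- dim(track)[2]
  out <- vapply(seq_len(n_lab), function(i) {
    xy <- track[, i, ]
    mu <- colMeans(xy)
    sqrt(mean((xy[, 1] - mu[1])^2 + (xy[, 2] - mu[2])^2))
  }, numeric(1))
  names(out) <- labels %||% dimnames(track)[[2]] %||% as.character(seq_len(n_lab))
  out
}
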