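# min-image distance matrix (rows of `a` x rows of `b`) on a square box
.mi_dist <- function(a, b, box) {
  dx <- abs(outer(a[, 1], b[, 1], "-")); dx <- pmin(dx, box - dx)
  dy <- abs(outer(a[, 2], b[, 2], "-")); dy <- pmin(dy, box - dy)
  sqrt(dx * dx + dy * dy)
}

.as_traj_list <- function(traj) {
  if (inherits(traj, "jm_trajectory")) return(list(traj))
  if (is.list(traj) && length(traj) &&
      all(vapply(traj, inherits, logical(1), "jm_trajectory")))
    return(traj)
  stop("expected a jm_trajectory or a list of them", call. = FALSE)
}

.check_species <- function(traj_list, species) {
  stopifnot(is.character(species), length(species) == 1L)
  for (tr in traj_list)
    if (!species %in% tr$species)
      stop("unknown species: no '", species, "' beads in trajectory",
           call. = FALSE)
  invisible(species)
}

#' Analysis configuration
#'
#' @param contact_cutoff Contact distance cutoff (A, default 6, inclusive).
#' @param gap_tolerance Frames of vacancy tolerated inside one association
#'   event when counting residence times (default 0: any unoccupied frame
#'   ends the event).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(contact_cutoff = 6, gap_tolerance = 0L) {
  stopifnot(contact_cutoff > 0, gap_tolerance >= 0)
  structure(list(contact_cutoff = contact_cutoff,
                 gap_tolerance = as.integer(gap_tolerance)),
            class = "analysis_config")
}

#' Per-residue, per-frame lipid contact counts
#'
#' For each protein anchor (TM bead and JM residues 1..L) and each frame,
#' counts the beads of `species` whose periodic minimum-image distance to
#' the anchor is at or below the cutoff (boundary inclusive). Replicates
#' are concatenated along the frame axis; the per-replicate frame counts
#' are retained so event statistics never bridge replicate boundaries.
#'
#' @param traj A `jm_trajectory` or list of replicates.
#' @param species Lipid species name present in the trajectory.
#' @param config An `analysis_config` (default: 6 A cutoff).
#' @return Object of class `contact_matrix`: integer `counts`
#'   (residues x frames, rownames = anchor labels), `species`, `cutoff`,
#'   `frame_interval`, `rep_frames`, `replicate_ids`, and the anchor table.
#' @export
count_contacts <- function(traj, species, config = analysis_config()) {
  trs <- .as_traj_list(traj)
  .check_species(trs, species)
  cutoff <- config$contact_cutoff
  blocks <- lapply(trs, function(tr) {
    sel <- which(tr$species == species)
    anc <- cbind(tr$anchors$x, tr$anchors$y)
    nf <- dim(tr$coords)[1]
    out <- matrix(0L, nrow(anc), nf)
    for (f in seq_len(nf)) {
      beads <- tr$coords[f, sel, , drop = FALSE]
      dim(beads) <- c(length(sel), 2L)
      d <- .mi_dist(anc, beads, tr$box_edge)
      out[, f] <- as.integer(rowSums(d <= cutoff))
    }
    out
  })
  counts <- do.call(cbind, blocks)
  rownames(counts) <- trs[[1]]$anchors$label
  structure(list(
    counts = counts,
    species = species,
    cutoff = cutoff,
    gap_tolerance = config$gap_tolerance,
    frame_interval = trs[[1]]$frame_interval,
    rep_frames = vapply(blocks, ncol, integer(1)),
    replicate_ids = vapply(trs, function(tr) tr$replicate_id, integer(1)),
    anchors = trs[[1]]$anchors
  ), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Contact matrix: ", nrow(x$counts), " residues x ", ncol(x$counts),
      " frames (", length(x$rep_frames), " replicate(s)), species ",
      x$species, ", cutoff ", x$cutoff, " A\n", sep = "")
  invisible(x)
}

.check_cm <- function(cm) {
  if (!inherits(cm, "contact_matrix"))
    stop("expected a contact_matrix", call. = FALSE)
  if (ncol(cm$counts) == 0L)
    stop("empty input: contact matrix has zero frames", call. = FALSE)
  invisible(cm)
}

#' Mean contacts per frame, per residue
#'
#' Arithmetic mean of the contact count over all concatenated frames
#' (frames weighted equally across replicates).
#'
#' @param cm A `contact_matrix`.
#' @return Named numeric vector, one value per residue.
#' @export
mean_contacts <- function(cm) {
  .check_cm(cm)
  rowMeans(cm$counts)
}

#' Occupancy fraction: percentage of frames with at least one contact
#'
#' @param cm A `contact_matrix`.
#' @return Named numeric vector of percentages in [0, 100].
#' @export
occupancy_fraction <- function(cm) {
  .check_cm(cm)
  100 * rowMeans(cm$counts >= 1L)
}

# merge vacancy gaps of length <= gap into the surrounding occupied runs
.merge_gaps <- function(occ, gap) {
  if (gap <= 0L || !any(occ)) return(occ)
  r <- rle(occ)
  k <- length(r$values)
  fill <- !r$values & r$lengths <= gap &
    seq_len(k) > 1L & seq_len(k) < k          # interior gaps only
  r$values[fill] <- TRUE
  inverse.rle(r)
}

#' Mean lipid residence time per residue
#'
#' Binarizes each residue's contact series (count >= 1), counts maximal
#' runs of consecutive occupied frames as association events (runs never
#' bridge replicate boundaries), and returns occupancy time divided by the
#' number of events. Residues with zero events get 0 and are flagged in
#' the `"no_events"` attribute.
#'
#' @param cm A `contact_matrix`.
#' @param frame_interval Time per frame (defaults to the value recorded in
#'   the matrix).
#' @return Named numeric vector of mean residence times, with attributes
#'   `"events"` (event counts) and `"no_events"` (logical).
#' @export
residence_time <- function(cm, frame_interval = cm$frame_interval) {
  .check_cm(cm)
  gap <- cm$gap_tolerance %||% 0L
  bounds <- c(0L, cumsum(cm$rep_frames))
  res <- apply(cm$counts >= 1L, 1L, function(occ) {
    events <- 0L
    occupied <- 0L
    for (b in seq_len(length(bounds) - 1L)) {
      seg <- occ[(bounds[b] + 1L):bounds[b + 1L]]
      seg <- .merge_gaps(seg, gap)
      r <- rle(seg)
      events <- events + sum(r$values)
      occupied <- occupied + sum(seg)
    }
    c(occupied, events)
  })
  occupied <- res[1L, ]
  events <- res[2L, ]
  rt <- ifelse(events > 0L, occupied * frame_interval / events, 0)
  names(rt) <- rownames(cm$counts)
  attr(rt, "events") <- stats::setNames(events, rownames(cm$counts))
  attr(rt, "no_events") <- stats::setNames(events == 0L, rownames(cm$counts))
  rt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean first-interaction-shell count of a species
#'
#' Counts, per frame, the beads of `species` whose minimum distance to the
#' whole protein anchor set is at or below `cutoff`, and averages over all
#' frames of all replicates.
#'
#' @param traj A `jm_trajectory` or list of replicates.
#' @param species Lipid species name.
#' @param cutoff Shell cutoff (A, default 6).
#' @return Numeric scalar: mean per-frame first-shell count.
#' @export
first_shell_count <- function(traj, species, cutoff = 6) {
  trs <- .as_traj_list(traj)
  .check_species(trs, species)
  per_frame <- unlist(lapply(trs, function(tr) {
    sel <- which(tr$species == species)
    anc <- cbind(tr$anchors$x, tr$anchors$y)
    nf <- dim(tr$coords)[1]
    vapply(seq_len(nf), function(f) {
      beads <- tr$coords[f, sel, , drop = FALSE]
      dim(beads) <- c(length(sel), 2L)
      d <- .mi_dist(anc, beads, tr$box_edge)
      sum(apply(d, 2L, min) <= cutoff)
    }, numeric(1))
  }))
  mean(per_frame)
}

#' Tidy per-residue contact summary
#'
#' Combines mean contacts, occupancy fraction and mean residence time for
#' one contact matrix into a long-format data frame.
#'
#' @param cm A `contact_matrix`.
#' @param receptor_id Receptor identifier recorded in the table.
#' @return Data frame with columns receptor, residue, position (JM
#'   position, NA for the TM bead), class, species, statistic, value.
#' @export
contact_summary <- function(cm, receptor_id = NA_character_) {
  .check_cm(cm)
  stats_list <- list(
    mean_contacts = mean_contacts(cm),
    occupancy_pct = occupancy_fraction(cm),
    residence_time = as.numeric(residence_time(cm))
  )
  lab <- rownames(cm$counts)
  pos <- ifelse(grepl("^JM", lab), suppressWarnings(as.integer(sub("^JM", "", lab))),
                NA_integer_)
  do.call(rbind, lapply(names(stats_list), function(s) {
    data.frame(receptor = receptor_id, residue = lab, position = pos,
               class = cm$anchors$class, species = cm$species,
               statistic = s, value = as.numeric(stats_list[[s]]),
               stringsAsFactors = FALSE)
  }))
}
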