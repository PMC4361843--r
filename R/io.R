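#' Read receptor models from FASTA and a TM-span annotation table
#'
#' Reads amino-acid sequences from a FASTA file and TM spans from a
#' delimited table with columns `receptor_id`, `tm_start`, `tm_end`
#' (1-based inclusive), and builds a `tmjm_model` per annotated receptor.
#' Receptors whose JM segment cannot be extracted (fewer than `jm_length`
#' residues after the TM helix) are skipped with a warning so family runs
#' continue; an annotation naming an absent sequence is an error.
#'
#' @param fasta_path Path to the FASTA file.
#' @param annotation_path Path to the annotation table (TSV/whitespace).
#' @param jm_length JM segment length (default 20).
#' @return Named list of `tmjm_model` objects.
#' @export
read_receptor_table <- function(fasta_path, annotation_path, jm_length = 20L) {
  if (!file.exists(fasta_path))
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.table(annotation_path, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("receptor_id", "tm_start", "tm_end")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  missing <- setdiff(ann$receptor_id, ids)
  if (length(missing))
    stop("reference error: no sequence for annotated receptor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  models <- list()
  for (i in seq_len(nrow(ann))) {
    id <- ann$receptor_id[i]
    seq <- as.character(seqs[[match(id, ids)]])
    m <- tryCatch(
      tmjm_model(id, seq, c(ann$tm_start[i], ann$tm_end[i]), jm_length),
      error = function(e) {
        warning("skipping receptor ", id, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(m)) models[[id]] <- m
  }
  models
}

#' Write a trajectory to disk
#'
#' Text format: comment header (`box_edge`, `frame_interval`, `seed`,
#' `replicate_id`, `n_frames`) followed by whitespace-delimited rows
#' `frame bead_id kind species_or_residue x y`. Anchor rows (kind
#' `anchor`, time-invariant) are written once with frame 0; lipid
#' coordinates use fixed 3-decimal precision (0.001 A, far below the bead
#' radius). Format `"rds"` is the exact binary medium.
#'
#' @param traj A `jm_trajectory`.
#' @param path Output file path.
#' @param format `"text"` (default) or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("text", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "jm_trajectory"))
  if (format == "rds") {
    saveRDS(traj, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(traj$coords)[1]
  nl <- dim(traj$coords)[2]
  writeLines(c(
    "# jmlipid trajectory v1",
    sprintf("# box_edge %.6g", traj$box_edge),
    sprintf("# frame_interval %.6g", traj$frame_interval),
    sprintf("# seed %d", traj$seed),
    sprintf("# replicate_id %d", traj$replicate_id),
    sprintf("# n_frames %d", nf),
    "frame bead_id kind species x y"), con)
  anc <- traj$anchors
  writeLines(sprintf("0 %d anchor %s %.3f %.3f", seq_len(nrow(anc)),
                     anc$label, anc$x, anc$y), con)
  if (nf > 0L) {
    frame <- rep(seq_len(nf) - 1L, each = nl)
    bead <- rep(seq_len(nl), times = nf)
    sp <- rep(traj$species, times = nf)
    xs <- as.vector(t(matrix(traj$coords[, , 1], nrow = nf)))
    ys <- as.vector(t(matrix(traj$coords[, , 2], nrow = nf)))
    writeLines(sprintf("%d %d lipid %s %.3f %.3f", frame, bead, sp, xs, ys),
               con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path File path (text or rds format; rds is detected by content).
#' @return A `jm_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ok <- tryCatch({
    obj <- readRDS(path)
    if (!inherits(obj, "jm_trajectory")) stop("not a trajectory")
    obj
  }, error = function(e) NULL)
  if (!is.null(ok)) return(ok)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop("parse error: missing header field '", key, "'",
                          call. = FALSE)
    as.numeric(sub(paste0("^# ", key, " "), "", ln[1]))
  }
  box <- getv("box_edge"); fi <- getv("frame_interval")
  seed <- as.integer(getv("seed")); rep_id <- as.integer(getv("replicate_id"))
  nf <- as.integer(getv("n_frames"))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (!length(body) || !grepl("^frame\\b", body[1]))
    stop("parse error: missing column header row", call. = FALSE)
  body <- body[-1]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 6L)
  if (length(bad))
    stop("parse error: malformed row ", bad[1], " of trajectory body",
         call. = FALSE)
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- c("frame", "bead_id", "kind", "species", "x", "y")
  num <- suppressWarnings(list(frame = as.integer(tab$frame),
                               bead = as.integer(tab$bead_id),
                               x = as.numeric(tab$x), y = as.numeric(tab$y)))
  if (anyNA(num$x) || anyNA(num$y) || anyNA(num$frame))
    stop("parse error: non-numeric coordinate near row ",
         which(is.na(num$x) | is.na(num$y) | is.na(num$frame))[1],
         call. = FALSE)
  is_anchor <- tab$kind == "anchor"
  anc <- tab[is_anchor, , drop = FALSE]
  aa <- ifelse(anc$species == "TM", NA_character_,
               NA_character_)  # residue letters not stored in text rows
  anchors <- data.frame(
    label = anc$species,
    residue = aa,
    class = NA_character_,
    charge = 0L,
    x = num$x[is_anchor], y = num$y[is_anchor],
    stringsAsFactors = FALSE)
  lip <- which(!is_anchor)
  nl <- if (nf > 0L) length(lip) / nf else 0L
  if (nf > 0L && (nl != round(nl)))
    stop("parse error: lipid row count ", length(lip),
         " not divisible by n_frames ", nf, call. = FALSE)
  nl <- as.integer(nl)
  coords <- array(NA_real_, dim = c(nf, nl, 2))
  species <- character(nl)
  if (nf > 0L && nl > 0L) {
    ord <- lip[order(num$frame[lip], num$bead[lip])]
    coords[, , 1] <- matrix(num$x[ord], nrow = nf, byrow = TRUE)
    coords[, , 2] <- matrix(num$y[ord], nrow = nf, byrow = TRUE)
    species <- tab$species[ord[seq_len(nl)]]
  }
  structure(list(coords = coords, species = species, anchors = anchors,
                 box_edge = box, frame_interval = fi, seed = seed,
                 replicate_id = rep_id),
            class = "jm_trajectory")
}

#' Write a contact matrix as a delimited table with a metadata header
#'
#' @param cm A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path) {
  .check_cm(cm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# species %s", cm$species),
    sprintf("# cutoff %.6g", cm$cutoff),
    sprintf("# frame_interval %.6g", cm$frame_interval),
    sprintf("# rep_frames %s", paste(cm$rep_frames, collapse = ","))), con)
  utils::write.table(cm$counts, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Write an RDF profile as CSV
#' @param rdf An `rdf_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rdf <- function(rdf, path) {
  stopifnot(inherits(rdf, "rdf_profile"))
  df <- data.frame(r = rdf$r, value = rdf$value, sd = rdf$sd,
                   species = rdf$species)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a density map as a plain matrix text file
#' @param dm A `density_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(dm, path) {
  stopifnot(inherits(dm, "density_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# species %s", dm$species),
               sprintf("# cell %.6g", dm$cell),
               sprintf("# box_edge %.6g", dm$box_edge)), con)
  utils::write.table(dm$occupancy, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write positional probabilities in a PWM-style text layout
#'
#' One row per position, one column per symbol (amino acid or class),
#' consumable by standard sequence-logo tools.
#'
#' @param prob Matrix with symbols in rows and positions in columns (as
#'   returned in `positional_residue_probability()$aa_freq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(prob, path) {
  stopifnot(is.matrix(prob))
  df <- data.frame(position = as.integer(colnames(prob) %||%
                                           seq_len(ncol(prob))),
                   t(prob), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
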