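#' Extract the juxtamembrane segment downstream of the TM helix
#'
#' Returns the `jm_length` residues immediately C-terminal of the annotated
#' transmembrane span. JM positions are numbered 1..jm_length starting at
#' the first residue after the helix.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param tm_span Integer pair `c(start, end)`, 1-based inclusive.
#' @param jm_length Number of JM residues to extract (default 20).
#' @return The JM sequence as a single string.
#' @export
extract_jm <- function(sequence, tm_span, jm_length = 20L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  tm_span <- as.integer(tm_span)
  jm_length <- as.integer(jm_length)
  n <- nchar(sequence)
  if (length(tm_span) != 2L || any(is.na(tm_span)) ||
      tm_span[1] < 1L || tm_span[2] > n || tm_span[1] > tm_span[2])
    stop("invalid TM span [", tm_span[1], ", ", tm_span[2],
         "] for sequence of length ", n, call. = FALSE)
  if (jm_length < 0L) stop("jm_length must be non-negative", call. = FALSE)
  if (jm_length == 0L) return("")
  remaining <- n - tm_span[2]
  if (remaining < jm_length)
    stop("truncated JM: only ", remaining, " residue(s) follow the TM span, ",
         jm_length, " required", call. = FALSE)
  substr(sequence, tm_span[2] + 1L, tm_span[2] + jm_length)
}

#' Build a TM-JM receptor model from sequence and TM annotation
#'
#' A `tmjm_model` couples a receptor's sequence with its TM span and the
#' derived JM segment: per-residue class and formal charge, and the net JM
#' charge (sum of +1 for R/K and -1 for D/E over the JM segment).
#'
#' @param receptor_id Identifier string.
#' @param sequence Full amino-acid sequence containing the TM-JM region.
#' @param tm_span Integer pair, 1-based inclusive TM helix span.
#' @param jm_length Number of JM residues modelled (default 20).
#' @return Object of class `tmjm_model` with fields `receptor_id`,
#'   `sequence`, `tm_span`, `jm_sequence`, `per_residue_class`,
#'   `per_residue_charge` and `net_jm_charge`.
#' @examples
#' m <- tmjm_model("toy", paste0(strrep("L", 25), "RKRKS", strrep("A", 15),
#'                               "GG"), c(3, 25))
#' m$net_jm_charge
#' @export
tmjm_model <- function(receptor_id, sequence, tm_span, jm_length = 20L) {
  jm <- extract_jm(sequence, tm_span, jm_length)
  aa <- strsplit(jm, "", fixed = TRUE)[[1]]
  if (length(aa)) .check_aa(aa)
  cls <- if (length(aa)) classify_residue(aa) else character(0)
  chg <- if (length(aa)) residue_charge(aa) else integer(0)
  structure(list(
    receptor_id = receptor_id,
    sequence = sequence,
    tm_span = as.integer(tm_span),
    jm_length = as.integer(jm_length),
    jm_sequence = jm,
    per_residue_class = cls,
    per_residue_charge = chg,
    net_jm_charge = sum(chg)
  ), class = "tmjm_model")
}

#' @export
print.tmjm_model <- function(x, ...) {
  cat("TM-JM model:", x$receptor_id, "\n")
  cat("  TM span:", x$tm_span[1], "-", x$tm_span[2], "\n")
  cat("  JM (", x$jm_length, " aa): ", x$jm_sequence, "\n", sep = "")
  cat("  net JM charge:", sprintf("%+d", x$net_jm_charge), "\n")
  invisible(x)
}

#' Net formal charge of the JM segment
#'
#' @param model A `tmjm_model`.
#' @return Integer: sum of per-residue charges over the JM segment.
#' @export
net_jm_charge <- function(model) {
  stopifnot(inherits(model, "tmjm_model"))
  model$net_jm_charge
}

#' In-silico neutralisation mutant: every basic JM residue to leucine
#'
#' Replaces each Arg and Lys in the JM segment with Leu (a residue of
#' comparable side-chain bulk but no charge) and rebuilds the model; the
#' TM span and flanking sequence are unchanged.
#'
#' @param model A `tmjm_model`.
#' @return A new `tmjm_model` with the mutated JM segment.
#' @export
mutate_basic_to_leu <- function(model) {
  stopifnot(inherits(model, "tmjm_model"))
  jm <- chartr("RK", "LL", model$jm_sequence)
  start <- model$tm_span[2] + 1L
  seq <- model$sequence
  if (nchar(jm))
    substr(seq, start, start + model$jm_length - 1L) <- jm
  tmjm_model(paste0(model$receptor_id, "_RK2L"), seq, model$tm_span,
             model$jm_length)
}

#' Synthetic TM-JM model with a tunable basic cluster
#'
#' Builds a fabricated receptor model whose JM segment carries `n_basic`
#' basic residues (alternating R/K) at its N-terminal end, the remainder
#' filled with an S/L polar-hydrophobic pattern. Used for family scans of
#' charge against lipid clustering; the TM helix is a generic 23-residue
#' hydrophobic stretch.
#'
#' @param n_basic Number of basic residues placed at JM positions
#'   1..n_basic (0 to jm_length).
#' @param jm_length JM segment length (default 20).
#' @param receptor_id Identifier (default derived from `n_basic`).
#' @return A `tmjm_model`.
#' @export
synthetic_tmjm <- function(n_basic, jm_length = 20L,
                           receptor_id = sprintf("SYN%02d", n_basic)) {
  n_basic <- as.integer(n_basic)
  jm_length <- as.integer(jm_length)
  stopifnot(n_basic >= 0L, n_basic <= jm_length)
  basics <- rep_len(c("R", "K"), jm_length)
  filler <- rep_len(c("S", "L"), jm_length)
  jm <- character(jm_length)
  if (n_basic > 0L) jm[seq_len(n_basic)] <- basics[seq_len(n_basic)]
  if (n_basic < jm_length)
    jm[(n_basic + 1L):jm_length] <- filler[seq_len(jm_length - n_basic)]
  tm <- strrep("L", 23L)
  seq <- paste0("MGSG", tm, paste(jm, collapse = ""), "GSGS")
  tmjm_model(receptor_id, seq, c(5L, 4L + 23L), jm_length)
}

# Synthetic INSR-like JM: basic cluster adjacent to the TM helix (five R/K,
# net +4), emulating the insulin-receptor JM charge pattern. Not the real
# UniProt sequence.
.insr_like_jm <- "RKRKLSGSKSLYPNSTGSEQ"

#' Synthetic INSR-like TM-JM model
#'
#' The package's default test receptor: a generic 23-residue hydrophobic TM
#' helix followed by a synthetic 20-residue JM segment with a basic cluster
#' at its start (five R/K, net charge +4), emulating the charge layout of
#' the insulin-receptor juxtamembrane region. This is a fabricated
#' sequence, not the UniProt INSR entry.
#'
#' @param jm_length JM segment length (default 20; shorter values truncate).
#' @return A `tmjm_model` with receptor_id `"INSR_like"`.
#' @export
insr_like_model <- function(jm_length = 20L) {
  tm <- strrep("L", 23L)
  seq <- paste0("MGSG", tm, .insr_like_jm, "GSGS")
  tmjm_model("INSR_like", seq, c(5L, 4L + 23L), jm_length)
}

#' Bundled manifest of the 58 human receptor tyrosine kinases
#'
#' Returns the receptor identifiers (HGNC-style gene symbols) of the 58
#' human RTKs, as bundled in `inst/extdata/rtk_manifest.txt`. Sequences are
#' not bundled; they are user-supplied inputs.
#'
#' @return Character vector of 58 receptor identifiers.
#' @export
rtk_manifest <- function() {
  path <- system.file("extdata", "rtk_manifest.txt", package = "jmlipid")
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
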