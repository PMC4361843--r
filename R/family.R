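#' Family-wide positional mean contacts
#'
#' Elementwise mean, over receptors, of per-JM-position mean contact
#' vectors: the sum over all receptors divided by the receptor count,
#' giving the family's mean contacts per frame at each JM position.
#'
#' @param per_receptor_profiles List (or matrix, receptors in rows) of
#'   numeric vectors of identical length (JM positions 1..L).
#' @return Numeric vector of per-position family means.
#' @export
positional_mean_contacts <- function(per_receptor_profiles) {
  if (is.matrix(per_receptor_profiles))
    per_receptor_profiles <- split(per_receptor_profiles,
                                   row(per_receptor_profiles))
  if (!length(per_receptor_profiles))
    stop("empty input: no receptor profiles", call. = FALSE)
  len <- vapply(per_receptor_profiles, length, integer(1))
  if (length(unique(len)) != 1L)
    stop("shape error: profiles have differing lengths (",
         paste(unique(len), collapse = ", "), ")", call. = FALSE)
  m <- do.call(rbind, lapply(per_receptor_profiles, as.numeric))
  colMeans(m)
}

#' Per-position residue-class and amino-acid probabilities
#'
#' For a set of equal-length JM sequences, returns at each position the
#' probability of each residue class (basic/acidic/polar/hydrophobic) and
#' the full 20-letter amino-acid frequency table — the numeric content of
#' a sequence logo.
#'
#' @param jm_sequences Character vector of equal-length JM sequences.
#' @return List with `class_prob` (4 x L matrix, classes in rows) and
#'   `aa_freq` (20 x L matrix); both columns sum to 1.
#' @export
positional_residue_probability <- function(jm_sequences) {
  stopifnot(is.character(jm_sequences), length(jm_sequences) >= 1L)
  len <- unique(nchar(jm_sequences))
  if (length(len) != 1L)
    stop("shape error: JM sequences have differing lengths (",
         paste(len, collapse = ", "), ")", call. = FALSE)
  mat <- do.call(rbind, strsplit(jm_sequences, "", fixed = TRUE))
  .check_aa(as.vector(mat))
  aa_levels <- sort(names(.residue_class_table))
  cls_levels <- residue_classes()
  aa_freq <- vapply(seq_len(len), function(j) {
    tab <- table(factor(mat[, j], levels = aa_levels))
    as.numeric(tab) / nrow(mat)
  }, numeric(length(aa_levels)))
  rownames(aa_freq) <- aa_levels
  colnames(aa_freq) <- seq_len(len)
  class_prob <- vapply(seq_len(len), function(j) {
    tab <- table(factor(classify_residue(mat[, j]), levels = cls_levels))
    as.numeric(tab) / nrow(mat)
  }, numeric(length(cls_levels)))
  rownames(class_prob) <- cls_levels
  colnames(class_prob) <- seq_len(len)
  list(class_prob = class_prob, aa_freq = aa_freq)
}

#' Lipid clustering propensity around the protein
#'
#' The mean per-frame fraction of a species' bead population lying within
#' `cutoff` of the protein anchor set, divided by the species' leaflet
#' mole fraction. A value of 1 means no enrichment over the bulk leaflet
#' composition.
#'
#' @param traj A `jm_trajectory` or list of replicates.
#' @param species Lipid species name.
#' @param leaflet A `leaflet_composition` giving the species' leaflet
#'   fraction.
#' @param cutoff First-shell cutoff (A, default 6).
#' @return Numeric scalar `C >= 0`.
#' @export
clustering_propensity <- function(traj, species, leaflet, cutoff = 6) {
  if (!inherits(leaflet, "leaflet_composition"))
    leaflet <- leaflet_composition(leaflet)
  if (!species %in% names(leaflet) || leaflet[[species]] <= 0)
    stop("species '", species, "' absent from the leaflet composition",
         call. = FALSE)
  trs <- .as_traj_list(traj)
  .check_species(trs, species)
  n_species <- sum(trs[[1]]$species == species)
  mean_shell <- first_shell_count(trs, species, cutoff)
  (mean_shell / n_species) / as.numeric(leaflet[[species]])
}

#' Correlation between clustering propensity and net JM charge
#'
#' Pearson (default) or Spearman correlation between the clustering
#' propensity of one species and the net JM charge across receptors,
#' restricted by default to receptors whose JM carries a net positive
#' charge.
#'
#' @param records Data frame with columns `receptor_id`, `species`,
#'   `propensity`, `net_jm_charge` (see [clustering_propensity()]).
#' @param species Species to correlate.
#' @param method "pearson" (default) or "spearman".
#' @param positive_only Restrict to net_jm_charge > 0 (default TRUE).
#' @return Numeric correlation with attribute `"n"` (records used); `NaN`
#'   with attribute `"degenerate" = TRUE` when propensity or charge has
#'   zero variance.
#' @export
charge_propensity_correlation <- function(records, species,
                                          method = c("pearson", "spearman"),
                                          positive_only = TRUE) {
  method <- match.arg(method)
  need <- c("receptor_id", "species", "propensity", "net_jm_charge")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sub <- records[records$species == species, , drop = FALSE]
  if (positive_only)
    sub <- sub[sub$net_jm_charge > 0, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("insufficient data: need >= 3 usable records, have ", nrow(sub),
         call. = FALSE)
  degenerate <- stats::sd(sub$propensity) == 0 || stats::sd(sub$net_jm_charge) == 0
  r <- if (degenerate) NaN else
    stats::cor(sub$propensity, sub$net_jm_charge, method = method)
  structure(r, n = nrow(sub), degenerate = degenerate)
}

#' Synthetic family scan of JM charge against lipid clustering
#'
#' Simulates a series of synthetic receptors whose JM segments carry an
#' increasing number of N-terminal basic residues (see [synthetic_tmjm()]),
#' measures the clustering propensity of each species, and returns the
#' propensity records for [charge_propensity_correlation()].
#'
#' @param n_basic Integer vector of basic-residue counts to scan.
#' @param composition A `leaflet_composition`.
#' @param config A `sim_config`.
#' @param species Species to measure (default PIP2 and PS).
#' @param n_replicates Replicates per receptor (default 1 at scan scale).
#' @param cutoff First-shell cutoff (A).
#' @return Data frame of propensity records (one row per receptor x
#'   species).
#' @export
family_charge_scan <- function(n_basic, composition, config,
                               species = c("PIP2", "PS"),
                               n_replicates = 1L, cutoff = 6) {
  out <- lapply(n_basic, function(k) {
    model <- synthetic_tmjm(k)
    trajs <- simulate_replicates(model, composition, config, n_replicates)
    do.call(rbind, lapply(species, function(sp) {
      data.frame(receptor_id = model$receptor_id, species = sp,
                 propensity = clustering_propensity(trajs, sp, composition,
                                                    cutoff),
                 net_jm_charge = model$net_jm_charge,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}
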