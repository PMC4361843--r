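# Headgroup-bead parameters for the lipid species handled by the emulator.
# Charges: PIP2 carries the MARTINI-like net -4 of the bis-phosphorylated
# headgroup, PS and GM3 -1, PC/PE/CHOL neutral. The paper states only the
# relative anionic strength (PIP2 strongly more negative than PS); exact
# valences are a modelling choice. Diffusion coefficients are uniform across
# species (no per-species values are reported for the source systems).
.lipid_table <- data.frame(
  name = c("PC", "PS", "PIP2", "PE", "GM3", "CHOL"),
  charge = c(0L, -1L, -4L, 0L, -1L, 0L),
  diffusion_coefficient = 1,   # Angstrom^2 per time unit
  bead_radius = 2.35,          # Angstrom; contact distance 4.7 A
  stringsAsFactors = FALSE
)

#' Lipid species parameter table
#'
#' Headgroup-bead parameters used by the membrane emulator: formal charge
#' (valence units), lateral diffusion coefficient (A^2 per time unit) and
#' bead radius (A).
#'
#' @param name Optional species name(s) to look up.
#' @return Data frame of species parameters (all species, or the rows
#'   requested).
#' @export
lipid_species <- function(name = NULL) {
  if (is.null(name)) return(.lipid_table)
  idx <- match(name, .lipid_table$name)
  if (anyNA(idx))
    stop("unknown lipid species: ", paste(name[is.na(idx)], collapse = ", "),
         call. = FALSE)
  .lipid_table[idx, , drop = FALSE]
}

#' Define a leaflet composition
#'
#' A named set of lipid mole fractions for one leaflet. Fractions must be
#' non-negative and sum to 1 (tolerance 1e-9).
#'
#' @param ... Named fractions, e.g. `PC = 0.8, PS = 0.1, PIP2 = 0.1`, or a
#'   single named numeric vector.
#' @return Object of class `leaflet_composition` (named numeric vector).
#' @examples
#' leaflet_composition(PC = 0.8, PS = 0.1, PIP2 = 0.1)
#' @export
leaflet_composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1]]) &&
      !is.null(names(args[[1]]))) {
    frac <- args[[1]]
  } else {
    frac <- unlist(args)
  }
  if (is.null(names(frac)) || any(!nzchar(names(frac))))
    stop("all fractions must be named by species", call. = FALSE)
  lipid_species(names(frac))  # validates species names
  if (any(frac < 0))
    stop("composition error: negative fraction", call. = FALSE)
  if (abs(sum(frac) - 1) > 1e-9)
    stop("composition error: fractions sum to ", format(sum(frac)),
         ", expected 1", call. = FALSE)
  structure(frac, class = "leaflet_composition")
}

#' @export
print.leaflet_composition <- function(x, ...) {
  cat("Leaflet composition:",
      paste(sprintf("%s %.3g", names(x), as.numeric(x)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Apportion lipid counts by largest remainder
#'
#' Converts fractional composition into integer species counts using the
#' largest-remainder (Hamilton) method; remainder ties are broken by
#' species-name lexicographic order so counts are deterministic.
#'
#' @param composition A `leaflet_composition`.
#' @param n_lipids Total number of lipids.
#' @return Named integer vector of per-species counts summing to
#'   `n_lipids`.
#' @examples
#' apportion_counts(leaflet_composition(PC = 0.8, PS = 0.1, PIP2 = 0.1), 200)
#' @export
apportion_counts <- function(composition, n_lipids) {
  if (!inherits(composition, "leaflet_composition"))
    composition <- leaflet_composition(composition)
  n_lipids <- as.integer(n_lipids)
  stopifnot(n_lipids >= 0L)
  quota <- as.numeric(composition) * n_lipids
  counts <- floor(quota)
  left <- n_lipids - sum(counts)
  if (left > 0L) {
    rem <- quota - counts
    # order by remainder (descending), ties by species name (C locale)
    ord <- order(-rem, names(composition), method = "radix")
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(counts), names(composition))
}
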