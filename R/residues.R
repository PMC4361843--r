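#' @useDynLib jmlipid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed four-class residue table. Histidine is treated as polar/neutral and
# Gly/Pro as non-polar; only Arg/Lys carry +1 and Asp/Glu -1 (termini
# uncharged: all models are mid-protein fragments).
.residue_class_table <- c(
  R = "basic", K = "basic",
  D = "acidic", E = "acidic",
  S = "polar", T = "polar", N = "polar", Q = "polar",
  C = "polar", Y = "polar", H = "polar", W = "polar",
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
  I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
  G = "hydrophobic", P = "hydrophobic"
)

.residue_charge_table <- c(R = 1L, K = 1L, D = -1L, E = -1L)

#' Residue classes used throughout the package
#'
#' @return Character vector of the four residue class labels.
#' @export
residue_classes <- function() c("basic", "acidic", "polar", "hydrophobic")

.check_aa <- function(aa) {
  if (!is.character(aa) || any(is.na(aa)) || any(nchar(aa) != 1L))
    stop("invalid residue: expected one-letter amino-acid codes", call. = FALSE)
  bad <- setdiff(unique(aa), names(.residue_class_table))
  if (length(bad))
    stop("invalid residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(aa)
}

#' Classify an amino acid into one of four physicochemical classes
#'
#' Residues are grouped as basic (R, K), acidic (D, E), polar
#' (S, T, N, Q, C, Y, H, W) or hydrophobic (A, V, L, I, M, F, G, P).
#' Histidine is counted as neutral/polar and glycine/proline as
#' hydrophobic (non-polar).
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Character vector of class labels, one per input residue.
#' @examples
#' classify_residue(c("R", "E", "L", "H"))
#' @export
classify_residue <- function(aa) {
  .check_aa(aa)
  unname(.residue_class_table[aa])
}

#' Formal charge of an amino-acid side chain
#'
#' Arg and Lys carry +1, Asp and Glu -1, every other standard residue 0
#' (His is treated as neutral).
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Integer vector of charges in \{-1, 0, +1\}.
#' @export
residue_charge <- function(aa) {
  .check_aa(aa)
  ch <- .residue_charge_table[aa]
  ch[is.na(ch)] <- 0L
  unname(ch)
}
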