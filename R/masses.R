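#' Average residue masses of the 20 canonical amino acids
#'
#' Average (not monoisotopic) residue masses in Da, i.e. the mass each residue
#' contributes to a polypeptide chain (free amino acid minus one water).
#' Values follow the standard IUPAC atomic-weight based tables used by
#' ExPASy-style mass calculators. Average masses are the right choice for
#' intact protein complexes of ~10^4-10^5 Da measured at resolution 15,000,
#' where isotope structure is unresolved.
#'
#' @format Named numeric vector, one entry per one-letter residue code.
#' @keywords internal
RESIDUE_AVERAGE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)

# average mass of H2O, added once per chain (N- and C-termini)
WATER_AVERAGE_MASS <- 18.01528

#' Average molecular mass of a polypeptide from its sequence
#'
#' Sums the average residue masses over the chain and adds one water for the
#' termini. This is the "theoretical mass from the amino acid sequence" used
#' to predict native-MS masses of phycobiliprotein subunits before any
#' post-translational-modification adjustment.
#'
#' @param sequence Character scalar; amino-acid sequence using the 20 canonical
#'   one-letter codes (case-insensitive). Must be non-empty.
#' @return Average mass in Da (numeric scalar).
#' @examples
#' sequence_average_mass("G")   # glycine, ~75.07 Da
#' sequence_average_mass("GG")  # ~132.12 Da
#' @export
sequence_average_mass <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single character string")
  if (nchar(sequence) == 0L)
    stop("empty sequence: cannot compute a mass")
  residues <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  m <- RESIDUE_AVERAGE_MASS[residues]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop(sprintf("unknown residue '%s' at position %d", residues[bad], bad))
  }
  sum(m) + WATER_AVERAGE_MASS
}
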