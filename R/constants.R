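# Physical constants and reference tables for the MIDA machinery.
#
# Natural isotope abundances are IUPAC-style representative values.  Each
# element's vector gives the probability of a nominal mass shift of
# 0, 1, 2, ... relative to the all-lightest isotopologue (36S sits at
# shift 4, hence the zero at shift 3).

.ISOTOPE_ABUNDANCE <- list(
  H = c(0.999885, 0.000115),
  C = c(0.9893, 0.0107),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

.ELEMENTS <- c("C", "H", "N", "O", "S")

# Residue (monomer) elemental compositions: amino acid minus one water.
# A free peptide adds one H2O on top of the residue sum.
.RESIDUE_COMPOSITION <- matrix(
  c(
    # C   H   N  O  S
      3,  5,  1, 1, 0,  # A
      6, 12,  4, 1, 0,  # R
      4,  6,  2, 2, 0,  # N
      4,  5,  1, 3, 0,  # D
      3,  5,  1, 1, 1,  # C
      5,  7,  1, 3, 0,  # E
      5,  8,  2, 2, 0,  # Q
      2,  3,  1, 1, 0,  # G
      6,  7,  3, 1, 0,  # H
      6, 11,  1, 1, 0,  # I
      6, 11,  1, 1, 0,  # L
      6, 12,  2, 1, 0,  # K
      5,  9,  1, 1, 1,  # M
      9,  9,  1, 1, 0,  # F
      5,  7,  1, 1, 0,  # P
      3,  5,  1, 2, 0,  # S
      4,  7,  1, 2, 0,  # T
     11, 10,  2, 1, 0,  # W
      9,  9,  1, 2, 0,  # Y
      5,  9,  1, 1, 0   # V
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    .ELEMENTS
  )
)

# Effective number of C-H positions per residue that equilibrate with body
# water during protein synthesis (the classic empirically derived table used
# throughout heavy-water proteomics; all values are study-overridable inputs).
.EXCHANGEABLE_SITES <- c(
  A = 4.00, R = 3.43, N = 1.89, D = 1.89, C = 1.62,
  E = 3.95, Q = 3.95, G = 2.06, H = 2.88, I = 1.00,
  L = 0.60, K = 0.54, M = 1.12, F = 0.32, P = 2.59,
  S = 2.61, T = 0.20, W = 0.08, Y = 0.42, V = 0.56
)

# Carbamidomethylation of cysteine (iodoacetamide alkylation): +C2H3NO.
.CARBAMIDOMETHYL <- c(C = 2, H = 3, N = 1, O = 1, S = 0)

#' Natural isotope abundance table
#'
#' Per-element probabilities of nominal mass shifts 0, 1, 2, ... used when
#' predicting peptide isotope envelopes. Values are fixed representative
#' natural abundances; studies that need different constants can pass their
#' own table to [theoretical_envelope()].
#'
#' @param element Optional element symbol (`"C"`, `"H"`, `"N"`, `"O"`, `"S"`).
#' @return A named list of numeric vectors, or a single vector if `element`
#'   is given.
#' @export
#' @examples
#' natural_isotope_abundances("C")
natural_isotope_abundances <- function(element = NULL) {
  if (is.null(element)) {
    return(.ISOTOPE_ABUNDANCE)
  }
  element <- match.arg(element, .ELEMENTS)
  .ISOTOPE_ABUNDANCE[[element]]
}

#' Residue elemental compositions
#'
#' Monomer (residue) compositions of the 20 standard amino acids, i.e. the
#' free amino acid minus one water.
#'
#' @return An integer matrix with one row per residue and columns
#'   C, H, N, O, S.
#' @export
residue_compositions <- function() {
  .RESIDUE_COMPOSITION
}

#' Default exchangeable-site table
#'
#' Effective number of C-H positions per residue that incorporate deuterium
#' from body water during protein synthesis. The shipped values are the
#' field-standard empirically derived table; they are deliberately an
#' explicit input so that results are reproducible under any choice
#' (see [read_site_table()] for file-based overrides).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
#' @examples
#' default_site_table()[c("G", "A")]
default_site_table <- function() {
  .EXCHANGEABLE_SITES
}
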