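# Amino-acid constants: the canonical alphabet, the eight physicochemical
# property scales driving the autocorrelation descriptors, and the seven
# Dubchak-style three-class attribute partitions driving the CTD descriptors.
# All scales are standardised (zero mean, unit SD over the 20 residues) before
# use, so only the ordering/contrast of each scale matters, not its units.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in the fixed alphabetical one-letter order
#' used throughout the package (descriptor blocks, dipeptide indexing).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Published per-residue property scales (AAindex-style), named in the
# A..Y alphabetical order above.  Sources: Eisenberg consensus hydrophobicity,
# Hopp-Woods hydrophilicity, side-chain residue mass, pK of the alpha-COOH and
# alpha-NH3+ groups, isoelectric point, Bhaskaran-Ponnuswamy average
# flexibility, Charton-Charton polarizability.
.aa_scale <- function(...) {
  x <- c(...)
  names(x) <- AA_ALPHABET
  x
}

#' Physicochemical property scales for autocorrelation descriptors
#'
#' Eight per-residue property scales (hydrophobicity, hydrophilicity, residue
#' mass, pK1, pK2, isoelectric point, average flexibility, polarizability).
#' Each is a named numeric vector over [AA_ALPHABET]. The descriptor code
#' standardises each scale to zero mean and unit SD across the 20 residues
#' before computing lagged autocorrelations.
#'
#' @format Named list of 8 numeric vectors of length 20.
#' @export
AA_PROPERTY_SCALES <- list(
  hydrophobicity = .aa_scale(
    0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38, -1.50, 1.06,
    0.64, -0.78, 0.12, -0.85, -2.53, -0.18, -0.26, 1.08, 0.81, 0.26),
  hydrophilicity = .aa_scale(
    -0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
    -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3),
  residue_mass = .aa_scale(
    15.0, 47.0, 59.0, 73.0, 91.0, 1.0, 82.0, 57.0, 73.0, 57.0,
    75.0, 58.0, 42.0, 72.0, 101.0, 31.0, 45.0, 43.0, 130.0, 107.0),
  pK1 = .aa_scale(
    2.35, 1.71, 1.88, 2.19, 2.58, 2.34, 1.78, 2.32, 2.20, 2.36,
    2.28, 2.18, 1.99, 2.17, 2.18, 2.21, 2.15, 2.29, 2.38, 2.20),
  pK2 = .aa_scale(
    9.87, 10.78, 9.60, 9.67, 9.24, 9.60, 8.97, 9.76, 8.90, 9.60,
    9.21, 9.09, 10.60, 9.13, 9.09, 9.15, 9.12, 9.74, 9.39, 9.11),
  pI = .aa_scale(
    6.11, 5.02, 2.98, 3.08, 5.91, 6.06, 7.64, 6.04, 9.47, 6.04,
    5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.60, 6.02, 5.88, 5.63),
  flexibility = .aa_scale(
    0.357, 0.346, 0.511, 0.497, 0.314, 0.544, 0.323, 0.462, 0.466, 0.365,
    0.295, 0.463, 0.509, 0.493, 0.529, 0.507, 0.444, 0.386, 0.305, 0.420),
  polarizability = .aa_scale(
    0.046, 0.128, 0.105, 0.151, 0.290, 0.000, 0.230, 0.186, 0.219, 0.186,
    0.221, 0.134, 0.131, 0.180, 0.291, 0.062, 0.108, 0.140, 0.409, 0.298)
)

#' Dubchak three-class attribute partitions for CTD descriptors
#'
#' Seven physicochemical attributes, each partitioning the 20 amino acids into
#' three classes (coded 1/2/3): hydrophobicity, normalized van der Waals
#' volume, polarity, polarizability, charge, secondary-structure propensity
#' and solvent accessibility. Each element is a list of three character
#' vectors; together they cover every residue exactly once.
#'
#' @format Named list of 7 attributes; each a list of 3 character vectors.
#' @export
AA_CTD_GROUPS <- list(
  hydrophobicity = list(
    c("R", "K", "E", "D", "Q", "N"),                  # polar
    c("G", "A", "S", "T", "P", "H", "Y"),             # neutral
    c("C", "L", "V", "I", "M", "F", "W")),            # hydrophobic
  vdw_volume = list(
    c("G", "A", "S", "T", "P", "D", "C"),             # 0 - 2.78
    c("N", "V", "E", "Q", "I", "L"),                  # 2.95 - 4.0
    c("M", "H", "K", "F", "R", "Y", "W")),            # 4.03 - 8.08
  polarity = list(
    c("L", "I", "F", "W", "C", "M", "V", "Y"),        # 4.9 - 6.2
    c("P", "A", "T", "G", "S"),                       # 8.0 - 9.2
    c("H", "Q", "R", "K", "N", "E", "D")),            # 10.4 - 13.0
  polarizability = list(
    c("G", "A", "S", "D", "T"),                       # 0 - 0.108
    c("C", "P", "N", "V", "E", "Q", "I", "L"),        # 0.128 - 0.186
    c("K", "M", "H", "F", "R", "Y", "W")),            # 0.219 - 0.409
  charge = list(
    c("K", "R"),                                      # positive
    c("A", "N", "C", "Q", "G", "H", "I", "L", "M",
      "F", "P", "S", "T", "W", "Y", "V"),             # neutral
    c("D", "E")),                                     # negative
  secondary_structure = list(
    c("E", "A", "L", "M", "Q", "K", "R", "H"),        # helix
    c("V", "I", "Y", "C", "W", "F", "T"),             # strand
    c("G", "N", "P", "S", "D")),                      # coil
  solvent_accessibility = list(
    c("A", "L", "F", "C", "G", "I", "V", "W"),        # buried
    c("R", "K", "Q", "E", "N", "D"),                  # exposed
    c("M", "S", "P", "T", "H", "Y"))                  # intermediate
)

# Residue -> class index (1/2/3) lookup for one CTD attribute.
.ctd_class_map <- function(attr_groups) {
  m <- integer(20)
  names(m) <- AA_ALPHABET
  for (k in 1:3) m[attr_groups[[k]]] <- k
  m
}
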