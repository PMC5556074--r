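# Reference tables used across the feature modules. Kept as plain R
# constants so they are transparent, diff-able and configurable by
# argument everywhere they are consumed.

#' Standard amino acids
#'
#' Three-letter and one-letter codes for the 20 standard amino acids, in
#' alphabetical one-letter order (the order used for all composition
#' vectors in the package).
#' @return Named character vector mapping three-letter to one-letter codes.
#' @export
standard_amino_acids <- function() {
  c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
    GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
    MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
    SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")
}

AA1 <- sort(unname(standard_amino_acids()))
AA3 <- names(standard_amino_acids())

# Common non-standard residues with a fixed parent standard residue.
# Anything not listed here and not standard is dropped with a warning.
NONSTANDARD_MAP <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
  SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
  MLY = "LYS", M3L = "LYS", KCX = "LYS", CME = "CYS",
  HSD = "HIS", HSE = "HIS", HSP = "HIS", HID = "HIS",
  HIE = "HIS", HIP = "HIS"
)

#' Van der Waals radii by element
#'
#' Bondi-style van der Waals radii (Angstrom) used by the
#' Shrake-Rupley quadrature. Unknown elements fall back to carbon.
#' @return Named numeric vector, Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, SE = 1.90)
}

#' Theoretical maximum residue SASA
#'
#' Theoretical Gly-X-Gly maximum solvent accessible surface areas
#' (Angstrom^2) per residue type (Tien et al. theoretical values), used
#' to normalize absolute SASA into relative accessibility. Any function
#' consuming this table accepts a replacement.
#' @return Named numeric vector over three-letter residue codes.
#' @export
max_sasa_reference <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

# Apolar residue set for the hydrophobic-contact rule (C-C pairs <= 4.5 A
# between residues of this set).
HYDROPHOBIC_SET <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

# Physicochemical scales for pseudo amino-acid composition (Chou's
# standard triplet): hydrophobicity, hydrophilicity (Hopp-Woods) and
# side-chain mass, over one-letter codes.
PAAC_HYDROPHOBICITY <- c(
  A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
  E = -0.74, Q = -0.85, G =  0.48, H = -0.40, I =  1.38,
  L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08)

PAAC_HYDROPHILICITY <- c(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
  E = 3.0, Q = 0.2, G = 0.0, H = -0.5, I = -1.8,
  L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
  S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)

PAAC_SIDECHAIN_MASS <- c(
  A = 15.0, R = 101.0, N = 58.0, D = 59.0, C = 47.0,
  E = 73.0, Q = 72.0, G = 1.0, H = 82.0, I = 57.0,
  L = 57.0, K = 73.0, M = 75.0, F = 91.0, P = 42.0,
  S = 31.0, T = 45.0, W = 130.0, Y = 107.0, V = 43.0)

# Backbone atom names excluded from side-chain SASA. Hydrogens named as
# backbone amide/alpha hydrogens are covered; side-chain hydrogens count
# with the side chain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3", "HN")

# Column names reserved for observation identity / labels in a feature
# table; everything else is a feature.
ID_COLUMNS <- c("complex", "chain", "resno", "icode", "resname", "ddg", "class")

#' Feature columns of a feature table
#'
#' @param table A feature table (data.frame with identity columns and
#'   numeric feature columns).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), ID_COLUMNS)
}
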