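# Amino-acid alphabets and packaged lookup tables.

# Canonical feature-column order: alphabetical by one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Fixed PSI-BLAST ASCII PSSM column order.
PSSM_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Three-letter -> one-letter map for standard residues plus common
# modified residues seen in PDB ATOM records (MSE is the frequent one).
AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

#' Background amino-acid frequencies
#'
#' The Robinson & Robinson (1991) background distribution over the 20
#' standard amino acids, in the package's canonical alphabetical order.
#' Used as the default background `p^a` for relative-entropy features.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  p <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  p <- p[AA_ALPHABET]
  p / sum(p)
}

#' Physicochemical property table
#'
#' Seven per-residue physicochemical descriptors (Meiler et al. 2001):
#' steric parameter (graph shape index), polarizability, normalized van der
#' Waals volume, hydrophobicity, isoelectric point, helix probability and
#' sheet probability. Rows follow the canonical alphabetical amino-acid
#' order.
#'
#' @return A 20 x 7 numeric matrix with residue rownames and property
#'   colnames.
#' @export
aa_physchem_table <- function() {
  vals <- rbind(
    A = c(1.28, 0.05, 1.00,  0.31, 6.11, 0.42, 0.23),
    C = c(1.77, 0.13, 2.43,  1.54, 6.35, 0.17, 0.41),
    D = c(1.60, 0.11, 2.78, -0.77, 2.95, 0.25, 0.20),
    E = c(1.56, 0.15, 3.78, -0.64, 3.09, 0.42, 0.21),
    F = c(2.94, 0.29, 5.89,  1.79, 5.67, 0.30, 0.38),
    G = c(0.00, 0.00, 0.00,  0.00, 6.07, 0.13, 0.15),
    H = c(2.99, 0.23, 4.66,  0.13, 7.69, 0.27, 0.30),
    I = c(4.19, 0.19, 4.00,  1.80, 6.04, 0.30, 0.45),
    K = c(1.89, 0.22, 4.77, -0.99, 9.99, 0.32, 0.27),
    L = c(2.59, 0.19, 4.00,  1.70, 6.04, 0.39, 0.31),
    M = c(2.35, 0.22, 4.43,  1.23, 5.71, 0.38, 0.32),
    N = c(1.60, 0.13, 2.95, -0.60, 6.52, 0.21, 0.22),
    P = c(2.67, 0.00, 2.72,  0.72, 6.80, 0.13, 0.34),
    Q = c(1.56, 0.18, 3.95, -0.22, 5.65, 0.36, 0.25),
    R = c(2.34, 0.29, 6.13, -1.01, 10.74, 0.36, 0.25),
    S = c(1.31, 0.06, 1.60, -0.04, 5.70, 0.20, 0.28),
    T = c(3.03, 0.11, 2.60,  0.26, 5.60, 0.21, 0.36),
    V = c(3.67, 0.14, 3.00,  1.22, 6.02, 0.27, 0.49),
    W = c(3.21, 0.41, 8.08,  2.25, 5.94, 0.32, 0.42),
    Y = c(2.94, 0.30, 6.47,  0.96, 5.66, 0.25, 0.41)
  )
  colnames(vals) <- c("steric", "polarizability", "volume", "hydrophobicity",
                      "isoelectric", "helix_prob", "sheet_prob")
  vals
}

canonicalize_residues <- function(x) {
  x <- toupper(x)
  bad <- !(strsplit(x, "")[[1]] %in% c(AA_ALPHABET, "X"))
  if (any(bad)) {
    chars <- strsplit(x, "")[[1]]
    chars[bad] <- "X"
    x <- paste(chars, collapse = "")
  }
  x
}
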