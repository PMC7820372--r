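# Built-in amino-acid constants and physicochemical tables.
# Table version: apofam-tables-1. Encoders record this id in their feature
# provenance; changing any value here requires bumping the version.

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes in alphabetical order, the ordering used by every
#' encoder in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

APOFAM_TABLE_VERSION <- "apofam-tables-1"

# Nine physicochemical properties used by the pseudo-amino-acid composition
# encoder. Values per residue, alphabetical order. Sources: Chou-style
# hydrophobicity scale; Hopp-Woods hydrophilicity; side-chain mass; pK1
# (alpha-COOH), pK2 (alpha-NH3+) and pI at 25 C from standard biochemistry
# tables; Charton steric parameter as a rigidity proxy; irreplaceability
# derived from genetic-code degeneracy (1 / number of codons); and the
# Bhaskaran-Ponnuswamy average flexibility index. Each row is standardized to
# zero mean / unit variance over the 20 residues before use, so only relative
# values matter.
.pseaac_properties_raw <- function() {
  p <- rbind(
    hydrophobicity = c( 0.62,  0.29, -0.90, -0.74,  1.19,  0.48, -0.40,  1.38,
                       -1.50,  1.06,  0.64, -0.78,  0.12, -0.85, -2.53, -0.18,
                       -0.05,  1.08,  0.81,  0.26),
    hydrophilicity = c(-0.5, -1.0,  3.0,  3.0, -2.5,  0.0, -0.5, -1.8,
                        3.0, -1.8, -1.3,  0.2,  0.0,  0.2,  3.0,  0.3,
                       -0.4, -1.5, -3.4, -2.3),
    mass           = c( 15,  47,  59,  73,  91,   1,  82,  57,
                        73,  57,  75,  58,  42,  72, 101,  31,
                        45,  43, 130, 107),
    pK1            = c(2.34, 1.96, 1.88, 2.19, 1.83, 2.34, 1.82, 2.36,
                       2.18, 2.36, 2.28, 2.02, 1.99, 2.17, 2.17, 2.21,
                       2.09, 2.32, 2.83, 2.20),
    pK2            = c(9.69, 10.28, 9.60, 9.67, 9.13, 9.60, 9.17, 9.60,
                       8.95,  9.60, 9.21, 8.80, 10.60, 9.13, 9.04, 9.15,
                       9.10,  9.62, 9.39, 9.11),
    pI             = c(6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02,
                       9.74, 5.98, 5.74, 5.41, 6.30, 5.65, 10.76, 5.68,
                       5.60, 5.96, 5.89, 5.66),
    rigidity       = c(0.52, 0.62, 0.76, 0.68, 0.70, 0.00, 0.70, 1.02,
                       0.68, 0.98, 0.78, 0.76, 0.36, 0.68, 0.68, 0.53,
                       0.50, 0.76, 0.70, 0.70),
    irreplaceability = 1 / c(4, 2, 2, 2, 2, 4, 2, 3, 2, 6,
                             1, 2, 4, 2, 6, 6, 4, 4, 1, 2),
    flexibility    = c(0.357, 0.346, 0.511, 0.497, 0.314, 0.544, 0.323, 0.462,
                       0.466, 0.365, 0.295, 0.463, 0.509, 0.493, 0.529, 0.507,
                       0.444, 0.386, 0.305, 0.420)
  )
  colnames(p) <- AA_ALPHABET
  p
}

# Property matrix standardized per row to mean 0 / variance 1 over the 20
# residues (population variance, the PseAAC convention).
pseaac_properties <- function() {
  p <- .pseaac_properties_raw()
  mu <- rowMeans(p)
  sdev <- sqrt(rowMeans((p - mu)^2))
  (p - mu) / sdev
}

# Eight CTD property partitions of the alphabet into three groups, used by the
# 188-dimensional encoder. Standard three-group divisions.
ctd_groupings <- function() {
  g <- list(
    hydrophobicity = c("RKEDQN",   "GASTPHY",  "CLVIMFW"),
    vdw_volume     = c("GASTPDC",  "NVEQIL",   "MHKFRYW"),
    polarity       = c("LIFWCMVY", "PATGS",    "HQRKNED"),
    polarizability = c("GASDT",    "CPNVEQIL", "KMHFRYW"),
    charge         = c("KR",       "ANCQGHILMFPSTWYV", "DE"),
    secondary_structure = c("EALMQKRH", "VIYCWFT", "GNPSD"),
    solvent_accessibility = c("ALFCGIVW", "RKQEND", "MPSTHY"),
    surface_tension = c("GQDNAHR", "KTSEC",   "ILMFPWYV")
  )
  lapply(g, function(x) lapply(strsplit(x, ""), identity))
}
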