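# Per-residue-type constants used for residue classification and node weights.

#' Three-letter codes of the 20 standard amino acids
#'
#' Order is alphabetical by three-letter code; this order also indexes the
#' rows/columns of energy tables (x3 secondary-structure states).
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# Aliases for modified residues mapped onto a standard parent type.
.res_alias <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HSD = "HIS",
                HSE = "HIS", HSP = "HIS", CSO = "CYS", SEP = "SER",
                TPO = "THR", PTR = "TYR")

.nucleotides <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DI")

.waters <- c("HOH", "WAT", "DOD", "H2O")

# Average residue (monomer-in-chain) masses, Da.
.res_mass <- c(
  ALA = 71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY = 57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO = 97.1167, SER = 87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL = 99.1326)

# Kyte-Doolittle hydropathy index.
.res_kd <- c(
  ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
  GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
  LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
  SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

# Grantham (1974) polarity.
.res_polarity <- c(
  ALA = 8.1, ARG = 10.5, ASN = 11.6, ASP = 13.0, CYS = 5.5,
  GLN = 10.5, GLU = 12.3, GLY = 9.0, HIS = 10.4, ILE = 5.2,
  LEU = 4.9, LYS = 11.3, MET = 5.7, PHE = 5.2, PRO = 8.0,
  SER = 9.2, THR = 8.6, TRP = 5.4, TYR = 6.2, VAL = 5.9)

# Theoretical maximum accessible surface area (A^2), Tien et al. (2013),
# used to turn absolute per-residue ASA into relative accessibility.
.res_max_asa <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Van der Waals radii (A) by element for the accessibility calculation.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                I = 1.98)

#' Residue property lookup tables
#'
#' Returns the per-residue-type scale used for a node-weight mode:
#' `mass` is the average residue (monomer) mass in Da, `hydrophobicity` the
#' Kyte-Doolittle hydropathy index, and `polarity` the Grantham polarity.
#'
#' @param mode One of `"mass"`, `"hydrophobicity"`, `"polarity"`.
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
residue_scale <- function(mode = c("mass", "hydrophobicity", "polarity")) {
  mode <- match.arg(mode)
  switch(mode,
         mass = .res_mass,
         hydrophobicity = .res_kd,
         polarity = .res_polarity)
}

# --- small vector-geometry helpers shared by the dihedral classifier and the
#     fixture generators ---

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) v / .vnorm(v)

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Torsion angle (degrees, in (-180, 180]) defined by points p1-p2-p3-p4.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place atom D given positions A, B, C, bond length |C-D|, angle B-C-D (deg)
# and dihedral A-B-C-D (deg): the standard internal-to-Cartesian step.
.place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(dih),
          -length * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
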