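# Internal constant tables: residue topology, radii, hydropathy, donors/acceptors.

# Side-chain heavy atoms in canonical PDB order for the 20 standard amino acids.
.SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.AA3 <- names(.SIDECHAIN_ATOMS)

.AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.AA1_TO_3 <- stats::setNames(names(.AA3_TO_1), .AA3_TO_1)

.NUC_DNA <- c("DA", "DC", "DG", "DT", "DU")
.NUC_RNA <- c("A", "C", "G", "U", "I")

# Residue name used for design-placeholder residues in PDB output.
.DESIGN_RESNAME <- "DSN"

# Kyte-Doolittle hydropathy (one-letter keys).
.KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Net side-chain charge at physiological pH (His treated as neutral).
.AA_CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0
)

# Van der Waals radii (Angstrom) by element, Bondi-style values.
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, X = 1.70
)

# Hydrophobic residues considered for surface-patch analysis.
.HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

# Hydrogen-bond donor heavy atoms (N/O carrying a proton) and their
# antecedent atoms, used for the donor-antecedent-acceptor angle.
.HB_DONORS <- list(
  "*:N"       = "CA",   # backbone amide (PRO excluded at runtime)
  "SER:OG"    = "CB",
  "THR:OG1"   = "CB",
  "TYR:OH"    = "CZ",
  "ASN:ND2"   = "CG",
  "GLN:NE2"   = "CD",
  "LYS:NZ"    = "CE",
  "ARG:NE"    = "CD",
  "ARG:NH1"   = "CZ",
  "ARG:NH2"   = "CZ",
  "HIS:ND1"   = "CG",
  "HIS:NE2"   = "CE1",
  "TRP:NE1"   = "CE2"
)

# Hydrogen-bond acceptor heavy atoms.
.HB_ACCEPTORS <- c(
  "*:O", "SER:OG", "THR:OG1", "TYR:OH", "ASN:OD1", "GLN:OE1",
  "ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2", "HIS:ND1", "HIS:NE2",
  "MET:SD"
)

# Charged-group atoms for salt-bridge detection.
.NEG_ATOMS <- c("ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2")
.POS_ATOMS <- c("LYS:NZ", "ARG:NE", "ARG:NH1", "ARG:NH2")
.POS_ATOMS_HIS <- c("HIS:ND1", "HIS:NE2")

# Ideal backbone covalent geometry (Engh-Huber-style averages).
.BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8
)

.element_of <- function(atom_name) {
  # First alphabetic character of a (left-stripped) PDB atom name; two-letter
  # elements are rare in the heavy-atom protein world handled here.
  nm <- toupper(gsub("[^A-Z].*$", "", gsub("^[0-9 ]+", "", toupper(atom_name))))
  el <- substr(nm, 1, 1)
  el[el == ""] <- "X"
  el
}
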