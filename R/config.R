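#' Default extraction configuration
#'
#' Returns the list of tunable parameters used throughout feature
#' extraction. Every threshold that defines an interaction class lives
#' here so alternative parameterisations can be dropped in without
#' touching code.
#'
#' @details Key entries:
#' \describe{
#'   \item{vdw_radii}{Named vector of Bondi-style van der Waals radii
#'     (\enc{Å}{A}) per element; \code{vdw_default} is used (with a
#'     warning) for elements absent from the table.}
#'   \item{hbond}{\code{d_max} (donor--acceptor distance ceiling,
#'     \enc{Å}{A}), \code{d_ideal} (distance at which the distance weight
#'     saturates), \code{alpha_min} (minimum donor angle, degrees).}
#'   \item{bands}{Distance-band offsets (added to the sum of vdW radii)
#'     separating repulsive, contact and dispersion shells:
#'     \code{vdw_outer} = 0.7, \code{london_outer} = 3.0.}
#'   \item{hydrophobic}{\code{cutoff} contact distance (\enc{Å}{A}) and
#'     \code{burial_rasa} relative-ASA threshold defining the protein
#'     interior.}
#'   \item{asa}{\code{probe} radius and \code{n_points} sphere samples for
#'     accessible-surface-area integration.}
#'   \item{kd_scale}{Kyte--Doolittle hydropathy per one-letter residue
#'     code over the 26-symbol alphabet.}
#'   \item{solvation}{Atomic solvation parameters
#'     (kcal/mol/\enc{Å²}{A^2}) per atom class, Eisenberg--McLachlan
#'     style.}
#'   \item{cpaasc_classes}{The 8-class side-chain partition and the
#'     fallback class for unknown symbols.}
#' }
#'
#' @return A named list of parameters.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$hbond$d_max
default_config <- function() {
  list(
    vdw_radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                  P = 1.80, SE = 1.90),
    vdw_default = 1.70,
    covalent_radii = c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, H = 0.31,
                       P = 1.07, SE = 1.20),
    covalent_tol = 0.45,
    hbond = list(d_max = 3.5, d_ideal = 2.6, alpha_min = 100),
    nonbonded_min_path = 5L,
    bands = list(vdw_outer = 0.7, london_outer = 3.0),
    hydrophobic = list(cutoff = 4.5, burial_rasa = 0.20),
    asa = list(probe = 1.4, n_points = 256L),
    neighbor_cutoff = 6.8,
    kd_scale = .kd_scale,
    solvation = c(C = 0.016, N = -0.006, O = -0.006, S = 0.021,
                  O_charged = -0.024, N_charged = -0.050, default = 0),
    max_asa = .max_asa,
    alphabet = .aa_alphabet,
    cpaasc_classes = .cpaasc_classes,
    cpaasc_fallback = "polar_uncharged"
  )
}

# 26-symbol alphabet: 20 standard residues plus U (Sec), O (Pyl),
# B/Z/J ambiguity codes and X unknown -- exactly the letters A-Z.
.aa_alphabet <- LETTERS

# Kyte-Doolittle hydropathy. Extended codes: U treated as Cys, O as Lys,
# J as the Leu/Ile mean, B/Z as their acidic/amide parents, X neutral.
.kd_scale <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  U =  2.5, O = -3.9, J =  4.15, B = -3.5, Z = -3.5, X = 0.0
)

# Maximum accessible surface (A^2) of residue X in an extended Gly-X-Gly
# tripeptide (theoretical values, Tien et al. 2013 convention); used to
# normalise per-residue ASA into relative exposure.
.max_asa <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174,
  U = 167, O = 236, J = 199, B = 194, Z = 224, X = 197
)

# Mutually exclusive 8-class partition of side-chain chemistry.
.cpaasc_classes <- list(
  aliphatic_apolar = c("A", "V", "L", "I", "J"),
  aromatic         = c("F", "W", "Y"),
  polar_uncharged  = c("N", "Q", "B", "Z", "X"),
  positive         = c("K", "R", "H", "O"),
  negative         = c("D", "E"),
  sulfur           = c("C", "M", "U"),
  hydroxyl         = c("S", "T"),
  special          = c("G", "P")
)

# 3-letter -> 1-letter residue table. MSE (selenomethionine) folds into
# M; the rare residues get dedicated symbols: SEC -> U, PYL -> O and
# MVA (N-methylvaline) -> J, the only letter not claimed by a standard
# residue or by U/O/B/Z/X.
.aa_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O", MVA = "J",
  ASX = "B", GLX = "Z", UNK = "X"
)

.water_resids <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")

# Heavy atoms that carry (or can carry) a polar hydrogen, per residue.
# Backbone N is handled separately (all residues except PRO).
.donor_atoms <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG", SEC = "SE"
)

# Lone-pair-bearing N/O acceptors per residue; backbone O/OXT are
# acceptors in every residue.
.acceptor_atoms <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1",
  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH"
)

# sp2-hybridised heavy atoms per residue template (side chains); the
# backbone carbonyl C/O and (via the planar peptide bond) backbone N are
# flagged in code for every residue.
.sp2_atoms <- list(
  ARG = c("CZ", "NE", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"),
  ASP = c("CG", "OD1", "OD2"),
  GLN = c("CD", "OE1", "NE2"),
  GLU = c("CD", "OE1", "OE2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
)

# Ring-member atoms per residue template; bonds internal to a ring are
# never rotatable.
.ring_atoms <- list(
  PRO = c("N", "CA", "CB", "CG", "CD"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

# Charged-atom templates for the solvation-parameter classes.
.charged_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.charged_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

# 1-letter -> 3-letter lookup (inverse of .aa_321, standard 20 + rare).
.aa_123 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", U = "SEC", O = "PYL", J = "MVA", B = "ASX",
  Z = "GLX", X = "UNK"
)
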