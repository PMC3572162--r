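# Model constants: bead inventory, charge rules, DNA bonded-term table,
# tail definitions and ion properties. Versioned so that builds are
# reproducible across releases.

MODEL_CONSTANTS_VERSION <- "1.0"

# physical constants (SI), used only to form the Bjerrum length
.ELEMENTARY_CHARGE <- 1.602176634e-19   # C
.EPSILON_0 <- 8.8541878128e-12          # F/m
.K_BOLTZMANN <- 1.380649e-23            # J/K

#' Bjerrum length
#'
#' Distance at which two unit charges in a continuum dielectric interact with
#' thermal energy kT; it is the Coulomb prefactor when energies are expressed
#' in kT and distances in Angstrom.
#'
#' @param epsilon_r relative permittivity of the medium (dimensionless).
#' @param temperature_K absolute temperature in kelvin.
#' @return Bjerrum length in Angstrom.
#' @examples
#' bjerrum_length(78, 298)
#' @export
bjerrum_length <- function(epsilon_r = 78, temperature_K = 298) {
  stopifnot(epsilon_r > 0, temperature_K > 0)
  lb_m <- .ELEMENTARY_CHARGE^2 /
    (4 * pi * .EPSILON_0 * epsilon_r * .K_BOLTZMANN * temperature_K)
  lb_m * 1e10
}

# residue charge rules: basic +1, acidic -1, all other standard residues 0
.AA_CHARGE <- c(
  LYS = 1, ARG = 1, ASP = -1, GLU = -1,
  ALA = 0, ASN = 0, CYS = 0, GLN = 0, GLY = 0, HIS = 0, ILE = 0, LEU = 0,
  MET = 0, PHE = 0, PRO = 0, SER = 0, THR = 0, TRP = 0, TYR = 0, VAL = 0
)

.AA_CODE1 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN", E = "GLU",
  G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS", M = "MET", F = "PHE",
  P = "PRO", S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

.NUC_RESIDUES <- c("DA", "DT", "DG", "DC", "A", "T", "G", "C", "U", "DU")

# core composition of one nucleosome core particle
NCP_INVENTORY <- list(
  n_core = 710, n_core_positive = 116, n_core_negative = 64, n_core_neutral = 530,
  core_charge = 52,
  n_tail_beads = 270, tail_charge = 94,
  n_dna_units = 74, n_dna_beads = 370, n_phosphates = 296, dna_charge = -296,
  n_total = 1350, total_charge = -150
)

# histone tails: per-copy bead counts as stated for H2A(N), H2B, H3, H4 and
# the short H2A C-terminal tail; two copies of each.  Synthetic sequences
# reproduce length and net charge (+8/+12/+14/+9/+4 per copy, x2 = +94e).
TAIL_DEF <- data.frame(
  type = c("H2A", "H2B", "H3", "H4", "H2A-C"),
  length = c(20L, 35L, 43L, 24L, 13L),
  net_charge = c(8L, 12L, 14L, 9L, 4L),
  stringsAsFactors = FALSE
)

# Tail/core split used when reading a crystal structure: the first
# `length` residues of each histone chain are the N-tail; additionally the
# last 13 residues of each H2A chain form the C-tail.  Positional (not
# residue-number) ranges keep the rule independent of deposited numbering.
TAIL_SPLIT_RULE <- list(h2a_c_length = 13L)

# chain identity map for nucleosome crystal structures (1KX5 convention)
HISTONE_CHAIN_MAP <- c(
  A = "H3", B = "H4", C = "H2A", D = "H2B",
  E = "H3", F = "H4", G = "H2A", H = "H2B"
)
DNA_CHAINS <- c("I", "J")

# bonded parameters
CORE_BOND_K <- 5        # kT/A^2, octamer elastic network
CORE_LINK_K <- 5        # kT/A^2, DNA central bead - core links
TAIL_BOND_K <- 5        # kT/A^2
TAIL_BOND_R0 <- 3.25    # A, peptide contour length per residue
TAIL_CHARGED_RADIUS <- 0.6  # A, hard radius of charged tail beads

# DNA five-bead unit: central bead D (bases+sugars of 2 bp) + 4 phosphates
DNA_RISE <- 6.8         # A, spacing of consecutive D beads
DNA_TWIST <- 72         # degrees of phosphate-frame rotation per unit
DNA_D_RADIUS <- 4       # A hard radius (effective 6 A)
DNA_P_RADIUS <- 1       # A hard radius (effective 3 A)
DNA_D_MASS <- 4         # reduced; all other beads have mass 1
DNA_P_CHARGE <- -1

# bond/angle table of the duplex (equilibrium value, force constant)
DNA_BOND_TABLE <- list(
  d_p       = c(r0 = 9.62, k = 25),   # phosphate - central bead
  d_d       = c(r0 = 6.8,  k = 25),   # consecutive central beads
  strand_pp = c(r0 = 6.75, k = 25),   # neighbouring phosphates along a strand
  minor_pp  = c(r0 = 13.2, k = 5)     # across the minor groove
)
DNA_ANGLE_TABLE <- list(
  ddd       = c(phi0 = 180, k = 50),  # backbone straightness
  strand    = c(phi0 = 149, k = 100), # along each phosphate strand
  pdp       = c(phi0 = 140, k = 100)  # between the two strands, at D
)

# DNA superhelix wrapped on the octamer: 1.75 left-handed turns
SUPERHELIX_TURNS <- 1.75
SUPERHELIX_PITCH <- 27   # A; radius follows from the 6.8 A unit spacing

# mobile ion species
ION_TABLE <- data.frame(
  species = c("K", "Mg", "CoHex", "Cl"),
  charge = c(1, 2, 3, -1),
  hard_radius = c(0, 0.5, 1.5, 0),
  stringsAsFactors = FALSE
)

# synthetic octamer core dimensions (cylindrical wedge), Angstrom
SYNTH_CORE_RADIUS <- 33
SYNTH_CORE_HEIGHT <- 52
SYNTH_WEDGE_FACTOR <- 0.15   # fractional height reduction on the thin side

ion_properties <- function(species) {
  i <- match(species, ION_TABLE$species)
  if (is.na(i)) {
    stop("unknown ion species '", species, "'; valid: ",
         paste(ION_TABLE$species, collapse = ", "), call. = FALSE)
  }
  ION_TABLE[i, ]
}
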