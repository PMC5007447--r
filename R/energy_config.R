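## Interaction-energy parameter tables. Everything here is configuration:
## users can override any entry via defaultEnergyConfig() modification.

#' Default energy and geometry configuration for graph construction
#'
#' Returns the full set of tunable parameters used by
#' \code{\link{buildAtomisticGraph}}: covalent dissociation energies and
#' covalent radii, the DREIDING-type hydrogen-bond term, Coulomb parameters
#' for salt bridges and LINK electrostatics, and the tabulated hydrophobic
#' potential-of-mean-force well. Energies are kJ/mol, distances Angstrom.
#' The propensity measure is invariant to a uniform rescaling of all
#' energies, so the unit choice is cosmetic.
#'
#' @section Components:
#' \describe{
#'   \item{covalent}{\code{energies}: named vector of mean bond dissociation
#'     energies per unordered element pair ("C|N" etc.); \code{radii}: named
#'     covalent radii per element; \code{radiusScale}: tolerance factor for
#'     distance-based topology fallback; \code{peptideMax}: sanity cap on
#'     the C(i)-N(i+1) peptide bond length.}
#'   \item{hbond}{\code{D0} well depth, \code{R0} equilibrium
#'     donor-acceptor distance of the 12-10 potential, \code{maxDA} maximum
#'     donor-acceptor distance, \code{minAngle} minimum donor-H-acceptor
#'     angle in degrees.}
#'   \item{saltbridge}{\code{maxDist} between charged-group N/O atoms,
#'     \code{dielectric} effective relative permittivity.}
#'   \item{electrostatic}{LINK-record edges: \code{dielectric},
#'     \code{defaultCharge} used when the PDB charge column is absent.}
#'   \item{hydrophobic}{\code{rmin}/\code{rmax} range for carbon/sulphur
#'     tethers and a tabulated well \code{table} (columns \code{r},
#'     \code{e}) interpolated linearly.}
#' }
#'
#' @return a nested list of parameters.
#' @export
defaultEnergyConfig <- function() {
  list(
    covalent = list(
      energies = c(
        "C|C" = 347, "C|N" = 305, "C|O" = 358, "C|H" = 413, "C|S" = 259,
        "H|N" = 391, "H|O" = 467, "H|S" = 347, "N|N" = 163, "N|O" = 201,
        "O|O" = 146, "S|S" = 266, "O|P" = 335, "C|P" = 264, "H|P" = 322,
        "O|SE" = 343, "C|SE" = 234, "H|SE" = 276, "N|P" = 290
      ),
      radii = c(
        H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
        SE = 1.20, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
        MG = 1.41, ZN = 1.22, CA = 1.76, FE = 1.32, MN = 1.39,
        "NA" = 1.66, K = 2.03, CU = 1.32, NI = 1.24, CO = 1.26
      ),
      radiusScale = 1.3,
      peptideMax = 2.5
    ),
    hbond = list(D0 = 39.7, R0 = 2.75, maxDA = 3.6, minAngle = 90),
    saltbridge = list(maxDist = 4.0, dielectric = 4.0),
    electrostatic = list(dielectric = 4.0, defaultCharge = 1),
    hydrophobic = list(
      rmin = 3.8, rmax = 8.0,
      table = data.frame(
        r = c(3.8, 4.2, 4.6, 5.2, 5.7, 6.4, 7.0, 7.6, 8.0),
        e = c(2.0, 2.8, 2.2, 0.8, 0.3, 1.0, 1.2, 0.5, 0.1)
      )
    ),
    kCoulomb = 1389.35   # kJ * Angstrom / mol for unit charges in vacuum
  )
}

## Heavy-atom covalent topology templates for the standard amino acids.
## Backbone N-CA, CA-C, C-O (+ C-OXT) is implied for every entry; the lists
## below are the side chains (CB onwards). Hydrogens are attached by
## distance, and the inter-residue peptide bond C(i)-N(i+1) is added for
## consecutive residues of a chain.
SIDECHAIN_TEMPLATES <- list(
  ALA = list(),
  ARG = list(c("CB","CG"), c("CG","CD"), c("CD","NE"), c("NE","CZ"),
             c("CZ","NH1"), c("CZ","NH2")),
  ASN = list(c("CB","CG"), c("CG","OD1"), c("CG","ND2")),
  ASP = list(c("CB","CG"), c("CG","OD1"), c("CG","OD2")),
  CYS = list(c("CB","SG")),
  GLN = list(c("CB","CG"), c("CG","CD"), c("CD","OE1"), c("CD","NE2")),
  GLU = list(c("CB","CG"), c("CG","CD"), c("CD","OE1"), c("CD","OE2")),
  GLY = list(),
  HIS = list(c("CB","CG"), c("CG","ND1"), c("CG","CD2"), c("ND1","CE1"),
             c("CD2","NE2"), c("CE1","NE2")),
  ILE = list(c("CB","CG1"), c("CB","CG2"), c("CG1","CD1")),
  LEU = list(c("CB","CG"), c("CG","CD1"), c("CG","CD2")),
  LYS = list(c("CB","CG"), c("CG","CD"), c("CD","CE"), c("CE","NZ")),
  MET = list(c("CB","CG"), c("CG","SD"), c("SD","CE")),
  PHE = list(c("CB","CG"), c("CG","CD1"), c("CG","CD2"), c("CD1","CE1"),
             c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ")),
  PRO = list(c("CB","CG"), c("CG","CD"), c("CD","N")),
  SER = list(c("CB","OG")),
  THR = list(c("CB","OG1"), c("CB","CG2")),
  TRP = list(c("CB","CG"), c("CG","CD1"), c("CG","CD2"), c("CD1","NE1"),
             c("NE1","CE2"), c("CD2","CE2"), c("CD2","CE3"), c("CE2","CZ2"),
             c("CE3","CZ3"), c("CZ2","CH2"), c("CZ3","CH2")),
  TYR = list(c("CB","CG"), c("CG","CD1"), c("CG","CD2"), c("CD1","CE1"),
             c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ"), c("CZ","OH")),
  VAL = list(c("CB","CG1"), c("CB","CG2"))
)

## Charged side-chain groups for salt-bridge detection: atom-level partial
## formal charges. Histidine contributes only when doubly protonated.
CHARGED_GROUPS <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1.0),
  ARG = c(NH1 = 0.5, NH2 = 0.5)
)
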