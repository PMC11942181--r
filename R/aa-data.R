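# Element and amino-acid reference data used by the topology builder and the
# hydration / SASA analyses. All lengths in nm, masses in g/mol (amu).

# Standard atomic masses.
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  Na = 22.990, Cl = 35.453
)

# Bondi van der Waals radii (nm), used by the Shrake-Rupley SASA kernel.
.BONDI_RADIUS <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
  Na = 0.227, Cl = 0.175
)

# Mass of one water molecule; single-bead (coarse) waters carry the whole
# molecular mass so that mass-density profiles are meaningful.
.WATER_MASS <- 18.0153

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

.AA1_FROM_3 <- stats::setNames(names(.AA3), unname(.AA3))

# Side-chain heavy atoms plus their polar-hydrogen counts for the
# ATOMISTIC_LITE resolution. `don`/`acc` flag hydrogen-bond donor/acceptor
# heavy atoms; `nh` is the number of polar hydrogens attached to a donor.
# Sulfur is treated as hydrogen-bond inert.
.side <- function(name, element, don = FALSE, acc = FALSE, nh = 0L) {
  data.frame(name = name, element = element, don = don, acc = acc, nh = nh,
             stringsAsFactors = FALSE)
}

.AA_SIDECHAIN <- list(
  GLY = NULL,
  ALA = .side("CB", "C"),
  VAL = rbind(.side("CB", "C"), .side("CG1", "C"), .side("CG2", "C")),
  LEU = rbind(.side("CB", "C"), .side("CG", "C"),
              .side("CD1", "C"), .side("CD2", "C")),
  ILE = rbind(.side("CB", "C"), .side("CG1", "C"),
              .side("CG2", "C"), .side("CD1", "C")),
  PRO = rbind(.side("CB", "C"), .side("CG", "C"), .side("CD", "C")),
  PHE = rbind(.side("CB", "C"), .side("CG", "C"), .side("CD1", "C"),
              .side("CD2", "C"), .side("CE1", "C"), .side("CE2", "C"),
              .side("CZ", "C")),
  TRP = rbind(.side("CB", "C"), .side("CG", "C"), .side("CD1", "C"),
              .side("CD2", "C"), .side("NE1", "N", don = TRUE, nh = 1L),
              .side("CE2", "C"), .side("CE3", "C"), .side("CZ2", "C"),
              .side("CZ3", "C"), .side("CH2", "C")),
  MET = rbind(.side("CB", "C"), .side("CG", "C"),
              .side("SD", "S"), .side("CE", "C")),
  SER = rbind(.side("CB", "C"),
              .side("OG", "O", don = TRUE, acc = TRUE, nh = 1L)),
  THR = rbind(.side("CB", "C"),
              .side("OG1", "O", don = TRUE, acc = TRUE, nh = 1L),
              .side("CG2", "C")),
  CYS = rbind(.side("CB", "C"), .side("SG", "S")),
  TYR = rbind(.side("CB", "C"), .side("CG", "C"), .side("CD1", "C"),
              .side("CD2", "C"), .side("CE1", "C"), .side("CE2", "C"),
              .side("CZ", "C"),
              .side("OH", "O", don = TRUE, acc = TRUE, nh = 1L)),
  ASN = rbind(.side("CB", "C"), .side("CG", "C"),
              .side("OD1", "O", acc = TRUE),
              .side("ND2", "N", don = TRUE, nh = 2L)),
  GLN = rbind(.side("CB", "C"), .side("CG", "C"), .side("CD", "C"),
              .side("OE1", "O", acc = TRUE),
              .side("NE2", "N", don = TRUE, nh = 2L)),
  ASP = rbind(.side("CB", "C"), .side("CG", "C"),
              .side("OD1", "O", acc = TRUE), .side("OD2", "O", acc = TRUE)),
  GLU = rbind(.side("CB", "C"), .side("CG", "C"), .side("CD", "C"),
              .side("OE1", "O", acc = TRUE), .side("OE2", "O", acc = TRUE)),
  LYS = rbind(.side("CB", "C"), .side("CG", "C"), .side("CD", "C"),
              .side("CE", "C"), .side("NZ", "N", don = TRUE, nh = 3L)),
  ARG = rbind(.side("CB", "C"), .side("CG", "C"), .side("CD", "C"),
              .side("NE", "N", don = TRUE, nh = 1L), .side("CZ", "C"),
              .side("NH1", "N", don = TRUE, nh = 2L),
              .side("NH2", "N", don = TRUE, nh = 2L)),
  HIS = rbind(.side("CB", "C"), .side("CG", "C"),
              .side("ND1", "N", don = TRUE, nh = 1L), .side("CD2", "C"),
              .side("CE1", "C"), .side("NE2", "N", acc = TRUE))
)

# Heavy-atom mass of one in-chain residue (backbone N, CA, C, O plus side
# chain); this is the coarse-bead mass at CA resolution.
.residue_heavy_mass <- function(res3) {
  bb <- .ELEMENT_MASS[["N"]] + 2 * .ELEMENT_MASS[["C"]] + .ELEMENT_MASS[["O"]]
  sc <- .AA_SIDECHAIN[[res3]]
  if (is.null(sc)) return(bb)
  bb + sum(.ELEMENT_MASS[sc$element])
}

.RESIDUE_MASS <- vapply(unname(.AA3), .residue_heavy_mass, numeric(1))

#' Load a bundled maximum-SASA reference table
#'
#' Per-residue maximum solvent-accessible surface areas used to normalise SASA
#' into relative solvent accessibility (RSA). Two empirically motivated
#' variants are shipped under `inst/extdata` (values in nm^2): `"empirical"`
#' (maxima observed in Gly-X-Gly stretches of real structures) and
#' `"theoretical"` (maxima of fully extended tripeptides). Either can be
#' overridden by passing a custom table to [rsa()].
#'
#' @param which `"empirical"` (default) or `"theoretical"`.
#' @return Named numeric vector, 3-letter residue code -> max SASA in nm^2.
#' @export
max_sasa_table <- function(which = c("empirical", "theoretical")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("max_sasa_", which, ".csv"),
                      package = "condstat", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$max_sasa_nm2, tab$residue)
}
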