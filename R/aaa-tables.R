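# Shared lookup tables and small helpers.

# three-letter -> one-letter codes for the 20 standard amino acids
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_1TO3 <- setNames(names(AA_3TO1), unname(AA_3TO1))

# default van der Waals radii (Angstrom); config-overridable in compute_sasa()
DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

# average residue masses (Da); water (18.02) is added once per chain
AA_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.0153

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residue identifier string
#'
#' Builds the canonical `"chain:numbericode"` identifier used throughout the
#' package (e.g. `"A:139"`).
#'
#' @param chain chain id
#' @param resno author residue number
#' @param icode insertion code ("" when absent)
#' @return character vector of residue ids
#' @export
residue_id <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste0(chain, ":", resno, icode, recycle0 = TRUE)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

stop_pegsite <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_pegsite <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
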