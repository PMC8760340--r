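# Physicochemical constants used across the package. Every table is pinned
# here so that derived quantities (mass, pI, hydropathy) are reproducible.

#' @name cdmine-constants
#' @title Pinned physicochemical tables
#' @description
#' `AA_STANDARD` is the 20-letter amino-acid alphabet; `AA_ALPHABET` adds the
#' ambiguity code `X` (permitted in scanning and alignment, rejected by
#' [compute_physchem()]). `AA_MONO_AVG_MASS` holds average residue masses in
#' Daltons (peptide-bonded residues; one water, `WATER_MASS`, is added per
#' chain). `PKA_SIDECHAIN` / `PKA_TERMINI` are the classic EMBOSS-style pKa
#' values used for the Henderson--Hasselbalch net-charge model behind the
#' isoelectric point, and `KYTE_DOOLITTLE` is the standard hydropathy index
#' used by the signal-peptide detector.
#' @keywords internal
NULL

AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

AA_ALPHABET <- c(AA_STANDARD, "X")

# Average (not monoisotopic) residue masses, Da.
AA_MONO_AVG_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)

WATER_MASS <- 18.0153

# EMBOSS-style pKa set (side chains and termini); one pinned table, on
# purpose: the isoelectric point is table-dependent.
PKA_SIDECHAIN <- c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5,
                   Y = 10.1)
PKA_TERMINI <- c(nterm = 8.6, cterm = 3.6)

# Kyte-Doolittle hydropathy index.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2, X = 0)

# Background amino-acid frequencies (rounded Robinson-Robinson style) used
# by the synthetic generator and by log-odds profile scoring.
AA_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.065)
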