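#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in alphabetical one-letter order. This is the
#' default row/column order of every [SubstitutionMatrix-class] object;
#' display-time reorderings (e.g. by row average) are presentation only.
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y")

ONE_TO_THREE <- structure(names(THREE_TO_ONE), names = unname(THREE_TO_ONE))

#' Theoretical maximum solvent accessible surface area per residue type
#'
#' Theoretically derived maximum accessibility values (square Angstrom) used
#' to normalise absolute residue SASA into relative solvent accessibility
#' (rASA), following the Tien et al. (2013) theoretical scale.
#'
#' @return Named numeric vector over [AA20] (Angstrom^2).
#' @export
maxAsaTable <- function() {
  c(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104, H = 224,
    I = 197, K = 236, L = 201, M = 224, N = 195, P = 159, Q = 225,
    R = 274, S = 155, T = 172, V = 174, W = 264, Y = 263)
}

#' Van der Waals radii used for numerical SASA
#'
#' Element-based heavy-atom radii (Angstrom). Hydrogens are ignored by the
#' SASA routine; elements not listed fall back to carbon.
#'
#' @return Named numeric vector (Angstrom).
#' @export
vdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
}

# Kyte-Doolittle hydropathy; used only by the synthetic generator to shape
# "conservative vs non-conservative" mean effects.
kdHydropathy <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Residue side-chain volumes (Zamyatnin, A^3); second axis of the generator's
# substitution distance.
aaVolume <- c(
  A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1,
  H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
  P = 112.7, Q = 143.8, R = 173.4, S = 89.0, T = 116.1, V = 140.0,
  W = 227.8, Y = 193.6)

#' Helix propensity scale
#'
#' Free-energy helix propensities relative to alanine (kcal/mol; larger means
#' less helix-favouring), after the experimentally derived consensus scale of
#' Pace & Scholtz (1998). Used as the default [PropensityScale] for
#' [helixPropensityCorrelation()].
#'
#' @param name Scale name; currently only `"pace-scholtz"` is shipped. Users
#'   can supply their own scale as a named numeric vector over [AA20].
#' @return Named numeric vector over [AA20] (kcal/mol relative to alanine).
#' @export
helixPropensityScale <- function(name = "pace-scholtz") {
  name <- match.arg(name)
  c(A = 0.00, L = 0.21, R = 0.21, M = 0.24, K = 0.26, Q = 0.39,
    E = 0.40, I = 0.41, W = 0.49, S = 0.50, Y = 0.53, F = 0.54,
    H = 0.61, V = 0.61, N = 0.65, T = 0.66, C = 0.68, D = 0.69,
    G = 1.00, P = 3.16)[AA20]
}
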