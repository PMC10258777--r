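# Physical constants and residue mass tables. Monoisotopic, 6-decimal values;
# versioned so downstream mass arithmetic is reproducible to 1e-4 Da.

#' Mass constants used throughout the package
#'
#' Monoisotopic masses (Da) of water, a proton, and the averagine-style
#' isotope spacing used for monoisotopic-peak error correction.
#'
#' @format A named numeric vector with elements `water`, `proton`, `isotope`.
#' @export
MASS_CONSTANTS <- c(
  water   = 18.010565,
  proton  = 1.00727646677,
  isotope = 1.00335
)

#' Monoisotopic amino-acid residue masses
#'
#' Residue (not free amino acid) masses in Da for the 20 standard residues.
#' Isoleucine and leucine are isobaric but kept as distinct symbols.
#'
#' @format Named numeric vector, one element per one-letter residue code.
#' @export
AA_MASSES <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Monosaccharide residue mass table
#'
#' Monoisotopic residue masses (Da, i.e. after loss of water on glycosidic
#' bond formation) for the monosaccharides supported in glycan compositions.
#'
#' @format Named numeric vector.
#' @export
MONOSACCHARIDES <- c(
  HexNAc = 203.079373,
  Hex    = 162.052824,
  Fuc    = 146.057909,
  NeuAc  = 291.095417,
  NeuGc  = 307.090331
)

# Canonical residue order used by the glycan formatter.
GLYCAN_RESIDUE_ORDER <- names(MONOSACCHARIDES)

#' Variable modification masses
#'
#' Monoisotopic mass deltas (Da) for the variable modifications considered
#' during peptide index construction: methionine oxidation, protein
#' N-terminal acetylation, and cysteinylation.
#'
#' @format Named numeric vector.
#' @export
VARIABLE_MODS <- c(
  ox_M      = 15.994915,
  acetyl_nt = 42.010565,
  cysteinyl = 119.004099
)

#' Default oxonium-ion panel
#'
#' Diagnostic low-mass glycan fragment ions used by the oxonium gate. HexNAc
#' fragment series, Hex, the HexNAc+Hex disaccharide, and the two NeuAc ions.
#'
#' @return A data.frame with columns `name` and `mz`.
#' @export
default_oxonium_panel <- function() {
  data.frame(
    name = c("HexNAc-C2H6O3", "HexNAc-2H2O-CH2O", "HexNAc-2H2O",
             "HexNAc-H2O", "HexNAc", "Hex", "HexHexNAc",
             "NeuAc-H2O", "NeuAc"),
    mz = c(126.0550, 138.0550, 168.0655, 186.0761, 204.0867,
           163.0601, 366.1395, 274.0921, 292.1027),
    stringsAsFactors = FALSE
  )
}

#' Monoisotopic mass of an unmodified peptide
#'
#' @param sequence Character vector of peptide sequences (uppercase).
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @export
peptide_mass <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    m <- AA_MASSES[aa]
    if (anyNA(m)) {
      stop("unknown residue(s) in peptide '", s, "': ",
           paste(unique(aa[is.na(m)]), collapse = ", "))
    }
    sum(m) + MASS_CONSTANTS[["water"]]
  }, numeric(1), USE.NAMES = FALSE)
}

# ppm tolerance window half-width in Da around a reference mass
ppm_tol_da <- function(mass, tol_ppm) abs(mass) * tol_ppm * 1e-6
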