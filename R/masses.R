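# Monoisotopic mass constants.
#
# Residue masses (mass of the residue as incorporated in a chain, i.e. the
# free molecule minus one water) derived from atomic monoisotopic masses
# (CODATA/IUPAC): H 1.007825032, C 12, N 14.003074005, O 15.994914620,
# S 31.972070690.

#' Monoisotopic residue masses of the 20 canonical amino acids
#'
#' Named numeric vector of amino-acid residue masses in Da (peptide-bonded
#' residue, i.e. free amino acid minus water).
#'
#' @format Named numeric vector, one entry per one-letter code.
#' @export
amino_acid_masses <- c(
  G =  57.02146372, A =  71.03711379, S =  87.03202841, P =  97.05276385,
  V =  99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

#' Monoisotopic residue masses of glycan monosaccharides
#'
#' Named numeric vector of monosaccharide residue masses in Da (glycosidic
#' condensation already subtracted): HexNAc, Hex, Fuc (deoxyhexose),
#' NeuAc (N-acetylneuraminic acid) and NeuGc (N-glycolylneuraminic acid).
#'
#' @format Named numeric vector with entries `hexnac`, `hex`, `fuc`,
#'   `neuac`, `neugc`.
#' @export
monosaccharide_masses <- c(
  hexnac = 203.07937252,
  hex    = 162.05282342,
  fuc    = 146.05790880,
  neuac  = 291.09541651,
  neugc  = 307.09033113
)

## mass of one water molecule, added once per peptide chain
WATER_MONO <- 18.01056468

## carbamidomethylation (iodoacetamide alkylation) of cysteine
CARBAMIDOMETHYL <- 57.02146372

#' Default fixed modifications
#'
#' Carbamidomethylation of cysteine (+57.021464 Da), the fixed modification
#' introduced by iodoacetamide alkylation prior to digestion.
#'
#' @return Named numeric vector mapping one-letter residue codes to mass
#'   shifts in Da.
#' @export
default_fixed_mods <- function() {
  c(C = CARBAMIDOMETHYL)
}

## residue order used throughout for glycan compositions
COMP_COLS <- c("hexnac", "hex", "fuc", "neuac", "neugc")

## split a sequence string into residues, validating against the canonical 20
.residues <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(res %in% names(amino_acid_masses)))
  if (length(bad)) {
    stop(
      "non-canonical residue(s) '", paste(unique(res[bad]), collapse = "', '"),
      "' in ", what, " at position(s) ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  res
}
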