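# Independent oracles: masses are summed from elemental formulas and atomic
# monoisotopic masses, never from the package's residue-mass tables; the
# peak-assignment oracle is a literal all-pairs scan.

ATOM <- c(H = 1.007825032, C = 12.0, N = 14.003074005, O = 15.994914620,
          S = 31.972070690)

## residue elemental formulas (free amino acid minus one water)
AA_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

## monosaccharide residue formulas (glycosidic water already removed)
GLYCAN_FORMULA <- list(
  hexnac = c(C = 8, H = 13, N = 1, O = 5, S = 0),
  hex    = c(C = 6, H = 10, N = 0, O = 5, S = 0),
  fuc    = c(C = 6, H = 10, N = 0, O = 4, S = 0),
  neuac  = c(C = 11, H = 17, N = 1, O = 8, S = 0),
  neugc  = c(C = 11, H = 17, N = 1, O = 9, S = 0)
)

formula_mass <- function(f) {
  sum(ATOM[names(f)] * f)
}

## carbamidomethyl adds C2H3NO per cysteine
oracle_peptide_mass <- function(seq, carbamidomethyl = TRUE) {
  res <- strsplit(seq, "")[[1]]
  f <- Reduce(`+`, AA_FORMULA[res])
  f <- f + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # terminal water
  if (carbamidomethyl) {
    ncys <- sum(res == "C")
    f <- f + ncys * c(C = 2, H = 3, N = 1, O = 1, S = 0)
  }
  formula_mass(f)
}

oracle_glycan_mass <- function(comp) {
  vapply(seq_len(nrow(comp)), function(i) {
    f <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
    for (nm in names(GLYCAN_FORMULA)) {
      f <- f + comp[[nm]][i] * GLYCAN_FORMULA[[nm]]
    }
    formula_mass(f)
  }, numeric(1))
}

random_aa_seq <- function(n) {
  paste(sample(names(AA_FORMULA), n, replace = TRUE), collapse = "")
}

random_compositions <- function(n, max_count = 8) {
  data.frame(
    hexnac = sample(0:max_count, n, replace = TRUE),
    hex = sample(0:max_count, n, replace = TRUE),
    fuc = sample(0:3, n, replace = TRUE),
    neuac = sample(0:4, n, replace = TRUE),
    neugc = sample(0:2, n, replace = TRUE)
  )
}

## literal all-pairs argmin-|ppm| assignment with the documented tie-breaks
brute_force_match <- function(peaks, table, tol_ppm) {
  ntypes <- rowSums(as.matrix(table[c("hexnac", "hex", "fuc", "neuac",
                                      "neugc")]) > 0)
  chosen <- rep(NA_integer_, nrow(peaks))
  n_cand <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ppm <- (peaks$mass[i] - table$mass) / table$mass * 1e6
    cand <- which(abs(ppm) <= tol_ppm)
    n_cand[i] <- length(cand)
    if (!length(cand)) next
    best <- cand[order(abs(ppm[cand]), ntypes[cand], table$mass[cand])][1]
    chosen[i] <- best
  }
  list(chosen = chosen, n_cand = n_cand)
}
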