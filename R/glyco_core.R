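# Protein sequence handling: sequon detection, in-silico digestion, and
# monoisotopic mass arithmetic for peptides, glycans and glycopeptides.

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a plain
#' named character vector; the full description line is preserved as the
#' name.
#'
#' @param path Path to a FASTA file (single- or multi-record).
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    stop("no sequences found in FASTA file: ", path, call. = FALSE)
  }
  out <- as.character(aa)
  names(out) <- names(aa)
  out
}

#' Find N-glycosylation sequons (N-X-S/T, X != P)
#'
#' Scans a protein sequence for the N-glycosylation consensus motif:
#' asparagine followed by any residue except proline, followed by serine or
#' threonine.
#'
#' @param sequence Single character string of one-letter amino-acid codes.
#' @return A data frame with columns `position` (1-based index of the
#'   asparagine) and `motif` (the three motif residues), ordered by
#'   ascending position. Zero rows when no sequon is present.
#' @examples
#' find_sequons("NGSNGT")
#' @export
find_sequons <- function(sequence) {
  res <- .residues(sequence)
  n <- length(res)
  if (n < 3L) {
    return(data.frame(position = integer(), motif = character(),
                      stringsAsFactors = FALSE))
  }
  i <- seq_len(n - 2L)
  hit <- res[i] == "N" & res[i + 1L] != "P" & res[i + 2L] %in% c("S", "T")
  pos <- i[hit]
  data.frame(
    position = pos,
    motif = vapply(pos, function(p) paste(res[p:(p + 2L)], collapse = ""), ""),
    stringsAsFactors = FALSE
  )
}

## cleavage residue sets per protease; cleavage is C-terminal to these
## residues, blocked when the next residue is proline
.cleavage_residues <- function(protease, chymo_residues = c("F", "W", "Y", "L")) {
  switch(protease,
    trypsin = c("K", "R"),
    chymotrypsin = chymo_residues,
    `trypsin+chymotrypsin` = union(c("K", "R"), chymo_residues),
    stop("unknown protease '", protease, "'", call. = FALSE)
  )
}

#' In-silico protease digestion
#'
#' Digests a protein sequence with trypsin (cleaves after K/R), chymotrypsin
#' (cleaves after F/W/Y/L by default) or both (union of cleavage sites).
#' Cleavage is suppressed before proline. Peptides with `0..max_missed`
#' missed cleavages are returned; the zero-missed-cleavage peptides
#' partition the input sequence.
#'
#' @param sequence Single character string of one-letter amino-acid codes.
#' @param protease One of `"trypsin"`, `"chymotrypsin"`,
#'   `"trypsin+chymotrypsin"`.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @param chymo_residues Chymotrypsin specificity residues; the default
#'   F/W/Y/L is the common low-specificity rule without methionine.
#' @return Data frame with columns `sequence`, `start`, `end` (1-based
#'   inclusive coordinates in the parent) and `missed_cleavages`.
#' @examples
#' digest("AKRPGK", "trypsin", max_missed = 0)
#' @export
digest <- function(sequence, protease = c("trypsin", "chymotrypsin",
                                          "trypsin+chymotrypsin"),
                   max_missed = 2L,
                   chymo_residues = c("F", "W", "Y", "L")) {
  protease <- match.arg(protease)
  if (!is.numeric(max_missed) || max_missed < 0) {
    stop("max_missed must be a non-negative integer", call. = FALSE)
  }
  res <- .residues(sequence)
  n <- length(res)
  if (n == 0L) stop("empty sequence", call. = FALSE)

  cleave_after <- .cleavage_residues(protease, chymo_residues)
  i <- seq_len(n - 1L)
  cuts <- i[res[i] %in% cleave_after & res[i + 1L] != "P"]
  bounds <- c(0L, cuts, n)

  nfrag <- length(bounds) - 1L
  out <- vector("list", as.integer(max_missed) + 1L)
  for (mc in 0:max_missed) {
    if (mc + 1L > nfrag) break
    first <- seq_len(nfrag - mc)
    start <- bounds[first] + 1L
    end <- bounds[first + mc + 1L]
    out[[mc + 1L]] <- data.frame(
      sequence = substring(sequence, start, end),
      start = start, end = end,
      missed_cleavages = mc,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water (18.010565 Da) plus
#' fixed-modification shifts.
#'
#' @param sequence Peptide sequence(s); character vector.
#' @param fixed_mods Named numeric vector of per-residue mass shifts in Da;
#'   defaults to carbamidomethyl cysteine (see [default_fixed_mods()]).
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' peptide_mass("GG")
#' @export
peptide_mass <- function(sequence, fixed_mods = default_fixed_mods()) {
  if (length(fixed_mods) && any(!is.finite(fixed_mods))) {
    stop("fixed modification shifts must be finite", call. = FALSE)
  }
  vapply(sequence, function(s) {
    res <- .residues(s, what = "peptide")
    m <- sum(amino_acid_masses[res]) + WATER_MONO
    if (length(fixed_mods)) {
      hits <- res[res %in% names(fixed_mods)]
      if (length(hits)) m <- m + sum(fixed_mods[hits])
    }
    m
  }, numeric(1), USE.NAMES = FALSE)
}

#' Construct a glycan composition
#'
#' @param hexnac,hex,fuc,neuac,neugc Non-negative integer residue counts.
#'   Vectors are recycled to a common length.
#' @return Data frame with one row per composition and columns `hexnac`,
#'   `hex`, `fuc`, `neuac`, `neugc`. The all-zero composition denotes an
#'   unglycosylated peptide.
#' @export
glycan_composition <- function(hexnac = 0L, hex = 0L, fuc = 0L,
                               neuac = 0L, neugc = 0L) {
  comp <- data.frame(hexnac = hexnac, hex = hex, fuc = fuc,
                     neuac = neuac, neugc = neugc)
  .check_composition(comp)
  comp
}

.check_composition <- function(comp) {
  if (is.numeric(comp) && !is.null(names(comp))) {
    comp <- as.data.frame(as.list(comp))
  }
  missing_cols <- setdiff(COMP_COLS, names(comp))
  if (length(missing_cols)) {
    stop("composition lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(comp[COMP_COLS])
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("composition counts must be non-negative integers", call. = FALSE)
  }
  comp
}

#' Neutral monoisotopic glycan mass
#'
#' Residue-mass sum of a glycan composition; glycosidic condensation is
#' already encoded in the monosaccharide residue masses, so the all-zero
#' composition has mass 0.
#'
#' @param comp Glycan composition: a data frame with columns
#'   `hexnac`, `hex`, `fuc`, `neuac`, `neugc` (one row per composition) or
#'   a named numeric vector.
#' @return Numeric vector of glycan residue masses in Da.
#' @examples
#' glycan_mass(glycan_composition(hexnac = 2, hex = 5)) # Man5
#' @export
glycan_mass <- function(comp) {
  comp <- .check_composition(comp)
  as.numeric(as.matrix(comp[COMP_COLS]) %*% monosaccharide_masses[COMP_COLS])
}

#' Neutral monoisotopic glycopeptide mass
#'
#' Sum of the peptide mass and the glycan residue-mass sum. The peptide must
#' contain at least one N-glycosylation sequon when the composition is
#' non-zero.
#'
#' @inheritParams peptide_mass
#' @inheritParams glycan_mass
#' @param require_sequon Check that a non-zero glycan sits on a peptide
#'   carrying a sequon (default `TRUE`). The sequon motif may extend beyond
#'   the peptide's C-terminus in the parent protein, so set this to `FALSE`
#'   when passing peptides whose trailing motif residues were cleaved off.
#' @return Neutral monoisotopic mass in Da.
#' @export
glycopeptide_mass <- function(sequence, comp,
                              fixed_mods = default_fixed_mods(),
                              require_sequon = TRUE) {
  comp <- .check_composition(comp)
  gm <- glycan_mass(comp)
  if (require_sequon && any(gm > 0)) {
    if (nrow(find_sequons(sequence)) == 0L && !grepl("N", sequence, fixed = TRUE)) {
      stop("peptide '", sequence, "' carries no sequon asparagine; ",
           "cannot attach an N-glycan", call. = FALSE)
    }
  }
  peptide_mass(sequence, fixed_mods) + gm
}

#' Default glycan composition bounds
#'
#' Per-monosaccharide count ranges spanning paucimannose through
#' tetra-antennary, doubly-fucosylated, fully sialylated complex glycans and
#' high-mannose structures.
#'
#' @return Named list of `c(min, max)` integer pairs for `hexnac`, `hex`,
#'   `fuc`, `neuac`, `neugc`.
#' @export
default_composition_bounds <- function() {
  list(hexnac = c(2L, 8L), hex = c(3L, 12L), fuc = c(0L, 2L),
       neuac = c(0L, 4L), neugc = c(0L, 2L))
}

## default biological plausibility constraints:
##  * hexnac == 2 -> oligomannose only: no fucose or sialic acid, hex 5..9
##  * hexnac  > 2 -> at most one sialic acid per antenna (hexnac - 2 antennae)
.default_constraint <- function(comp) {
  sia <- comp$neuac + comp$neugc
  mannose_ok <- comp$hexnac != 2L |
    (comp$fuc == 0L & sia == 0L & comp$hex >= 5L & comp$hex <= 9L)
  sia_ok <- comp$hexnac <= 2L | sia <= pmax(comp$hexnac - 2L, 0L)
  mannose_ok & sia_ok
}

#' Enumerate glycan compositions
#'
#' Exhaustive Cartesian enumeration of glycan compositions within
#' per-monosaccharide bounds, filtered by a plausibility constraint. The
#' default constraint set admits oligomannose glycans (HexNAc2, Hex 5-9, no
#' fucose or sialic acid) and complex glycans with at most one sialic acid
#' per antenna (antennae approximated as HexNAc - 2).
#'
#' @param bounds Named list of `c(min, max)` pairs, as
#'   [default_composition_bounds()].
#' @param constraints `"default"` for the constraint set above, `"none"` for
#'   unconstrained enumeration, or a predicate `function(comp)` returning a
#'   logical vector over the rows of a composition data frame.
#' @return Composition data frame ordered lexicographically by
#'   (hexnac, hex, fuc, neuac, neugc); may have zero rows.
#' @export
enumerate_compositions <- function(bounds = default_composition_bounds(),
                                   constraints = "default") {
  if (!all(COMP_COLS %in% names(bounds))) {
    stop("bounds must name all of: ", paste(COMP_COLS, collapse = ", "),
         call. = FALSE)
  }
  rng <- lapply(bounds[COMP_COLS], function(b) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1] > b[2] || any(b < 0)) {
      stop("each bound must be c(min, max) with 0 <= min <= max",
           call. = FALSE)
    }
    seq.int(b[1], b[2])
  })
  comp <- expand.grid(rng, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(comp) <- COMP_COLS

  keep <- if (identical(constraints, "default")) {
    .default_constraint(comp)
  } else if (identical(constraints, "none")) {
    rep(TRUE, nrow(comp))
  } else if (is.function(constraints)) {
    constraints(comp)
  } else {
    stop("constraints must be \"default\", \"none\" or a function",
         call. = FALSE)
  }
  comp <- comp[keep, , drop = FALSE]
  comp <- comp[do.call(order, comp), , drop = FALSE]
  rownames(comp) <- NULL
  comp
}

#' Build the theoretical glycopeptide table
#'
#' Digests a protein, locates its sequons, and attaches every enumerated
#' glycan composition to every sequon-covering peptide, yielding the table
#' of theoretical neutral monoisotopic glycopeptide masses that deconvoluted
#' peak lists are matched against. Unglycosylated (zero-composition) rows
#' are emitted once per sequon-containing peptide; their `site` is `NA` when
#' the peptide spans more than one sequon, and such rows are excluded from
#' per-site normalization downstream.
#'
#' @inheritParams digest
#' @inheritParams enumerate_compositions
#' @param fixed_mods Named numeric vector of fixed modification shifts.
#' @param include_unglycosylated Emit zero-composition rows for
#'   sequon-containing peptides (default `TRUE`).
#' @return Data frame with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`, `site`, `n_sequons`, the five composition counts,
#'   and `mass`.
#' @export
build_glycopeptide_table <- function(sequence,
                                     protease = c("trypsin", "chymotrypsin",
                                                  "trypsin+chymotrypsin"),
                                     max_missed = 2L,
                                     bounds = default_composition_bounds(),
                                     constraints = "default",
                                     fixed_mods = default_fixed_mods(),
                                     include_unglycosylated = TRUE,
                                     chymo_residues = c("F", "W", "Y", "L")) {
  protease <- match.arg(protease)
  peps <- digest(sequence, protease, max_missed, chymo_residues)
  sequons <- find_sequons(sequence)
  comps <- enumerate_compositions(bounds, constraints)
  comp_masses <- glycan_mass(comps)

  rows <- vector("list", nrow(peps) * 2L)
  k <- 0L
  for (p in seq_len(nrow(peps))) {
    covered <- sequons$position[sequons$position >= peps$start[p] &
                                sequons$position <= peps$end[p]]
    nseq <- length(covered)
    if (nseq == 0L) next
    pmass <- peptide_mass(peps$sequence[p], fixed_mods)
    base <- peps[p, , drop = FALSE]
    rownames(base) <- NULL
    if (include_unglycosylated) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        peptide = base$sequence, start = base$start, end = base$end,
        missed_cleavages = base$missed_cleavages,
        site = if (nseq == 1L) covered else NA_integer_,
        n_sequons = nseq,
        hexnac = 0L, hex = 0L, fuc = 0L, neuac = 0L, neugc = 0L,
        mass = pmass, stringsAsFactors = FALSE
      )
    }
    if (nrow(comps)) {
      for (s in covered) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          peptide = base$sequence, start = base$start, end = base$end,
          missed_cleavages = base$missed_cleavages,
          site = s, n_sequons = nseq,
          comps, mass = pmass + comp_masses,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else data.frame(
    peptide = character(), start = integer(), end = integer(),
    missed_cleavages = integer(), site = integer(), n_sequons = integer(),
    hexnac = integer(), hex = integer(), fuc = integer(), neuac = integer(),
    neugc = integer(), mass = numeric(), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a theoretical glycopeptide table as TSV
#'
#' @param table Output of [build_glycopeptide_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_glycopeptide_table <- function(table, path) {
  cols <- c("peptide", "start", "end", "site", "hexnac", "hex", "fuc",
            "neuac", "neugc", "mass")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(table[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
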