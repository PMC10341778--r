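# Sequon detection, digestion and mass arithmetic.

test_that("sequon detection follows the N-X-S/T rule with proline exclusion", {
  expect_equal(find_sequons("NGS")$position, 1L)
  expect_equal(nrow(find_sequons("NPS")), 0L)
  expect_equal(find_sequons("NGSNGT")$position, c(1L, 4L))
  expect_equal(find_sequons("NGSNGT")$motif, c("NGS", "NGT"))
  expect_equal(nrow(find_sequons("AG")), 0L)
  expect_error(find_sequons("NXS"), "'X'.*position")
})

test_that("sequon detection agrees with a brute-force window scan", {
  set.seed(71)
  alphabet <- c(names(glycoprofiler::amino_acid_masses))
  for (rep in 1:100) {
    s <- paste(sample(c(alphabet, "N", "S", "T", "P"), sample(10:80, 1),
                      replace = TRUE), collapse = "")
    res <- strsplit(s, "")[[1]]
    expected <- integer(0)
    for (i in seq_len(max(0, length(res) - 2))) {
      if (res[i] == "N" && res[i + 1] != "P" && res[i + 2] %in% c("S", "T")) {
        expected <- c(expected, i)
      }
    }
    expect_equal(find_sequons(s)$position, expected)
  }
})

test_that("trypsin digestion respects K/R specificity and proline protection", {
  d0 <- digest("AKRPGK", "trypsin", max_missed = 0)
  expect_equal(d0$sequence, c("AK", "RPGK"))
  expect_equal(d0$start, c(1L, 3L))
  expect_equal(d0$end, c(2L, 6L))

  d1 <- digest("AKRPGK", "trypsin", max_missed = 1)
  expect_setequal(d1$sequence, c("AK", "RPGK", "AKRPGK"))
  expect_equal(d1$missed_cleavages[d1$sequence == "AKRPGK"], 1L)

  expect_equal(digest("GGG", "trypsin", max_missed = 0)$sequence, "GGG")
  expect_error(digest("", "trypsin"), "single character|empty")
})

test_that("chymotrypsin and combined digestion use the configured residue sets", {
  expect_equal(digest("GGFGGWGG", "chymotrypsin", max_missed = 0)$sequence,
               c("GGF", "GGW", "GG"))
  ## proline protects chymotryptic sites too
  expect_equal(digest("GGFPGG", "chymotrypsin", max_missed = 0)$sequence,
               "GGFPGG")
  ## combined digestion cuts at the union of sites
  both <- digest("GKGFGG", "trypsin+chymotrypsin", max_missed = 0)
  expect_equal(both$sequence, c("GK", "GF", "GG"))
  ## configurable specificity: drop L from the set
  noL <- digest("GGLGG", "chymotrypsin", max_missed = 0,
                chymo_residues = c("F", "W", "Y"))
  expect_equal(noL$sequence, "GGLGG")
})

test_that("zero-missed-cleavage peptides partition random sequences", {
  set.seed(72)
  for (rep in 1:100) {
    s <- random_aa_seq(sample(5:120, 1))
    for (prot in c("trypsin", "chymotrypsin", "trypsin+chymotrypsin")) {
      d <- digest(s, prot, max_missed = 2)
      d0 <- d[d$missed_cleavages == 0, ]
      expect_identical(paste(d0$sequence, collapse = ""), s)
      expect_equal(d0$start[1], 1L)
      expect_equal(d0$end[nrow(d0)], nchar(s))
    }
  }
})

test_that("peptide masses match hand-derived values", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-7)
  expect_equal(peptide_mass("GG"), 132.05349, tolerance = 1e-7)
  ## carbamidomethyl cysteine applied as fixed modification
  expect_equal(peptide_mass("C"), 178.04121, tolerance = 1e-7)
  expect_equal(peptide_mass("C", fixed_mods = NULL), 121.01975,
               tolerance = 1e-5)
  expect_error(peptide_mass("GBZ"), "non-canonical")
})

test_that("peptide mass is additive up to one condensation water", {
  set.seed(73)
  for (rep in 1:50) {
    p1 <- random_aa_seq(sample(1:25, 1))
    p2 <- random_aa_seq(sample(1:25, 1))
    expect_equal(peptide_mass(paste0(p1, p2)),
                 peptide_mass(p1) + peptide_mass(p2) - 18.010565,
                 tolerance = 1e-6)
  }
})

test_that("glycan masses match residue-sum values", {
  expect_equal(glycan_mass(glycan_composition(hexnac = 2, hex = 3)),
               892.31722, tolerance = 1e-5)
  expect_equal(glycan_mass(glycan_composition(hexnac = 2, hex = 5)),
               1216.42287, tolerance = 1e-5)
  expect_equal(glycan_mass(glycan_composition()), 0)
  expect_error(glycan_composition(hexnac = -1), "non-negative")
  expect_error(glycan_mass(data.frame(hexnac = 1)), "lacks column")
})

test_that("glycopeptide mass is the peptide + glycan sum and checks sequons", {
  man5 <- glycan_composition(hexnac = 2, hex = 5)
  ## sequon-free dipeptide with the sequon check relaxed: pure additivity
  expect_equal(glycopeptide_mass("GG", man5, require_sequon = FALSE),
               1348.47636, tolerance = 1e-5)
  expect_error(glycopeptide_mass("GG", man5), "no sequon")
  ## zero composition is the identity
  expect_equal(glycopeptide_mass("NGSK", glycan_composition()),
               peptide_mass("NGSK"))
  ## linearity: mass(p, a) + glycan_mass(b) == mass(p, a + b)
  a <- glycan_composition(hexnac = 3, hex = 4, fuc = 1)
  b <- glycan_composition(hexnac = 1, hex = 2, neuac = 2)
  ab <- glycan_composition(hexnac = 4, hex = 6, fuc = 1, neuac = 2)
  expect_equal(glycopeptide_mass("NGSK", a) + glycan_mass(b),
               glycopeptide_mass("NGSK", ab), tolerance = 1e-9)
})

test_that("composition enumeration is exhaustive, ordered and constrained", {
  few <- enumerate_compositions(
    bounds = list(hexnac = c(2, 2), hex = c(3, 5), fuc = c(0, 0),
                  neuac = c(0, 0), neugc = c(0, 0)),
    constraints = "none"
  )
  expect_equal(nrow(few), 3L)
  expect_equal(few$hex, 3:5)

  zero <- enumerate_compositions(
    bounds = list(hexnac = c(0, 0), hex = c(0, 0), fuc = c(0, 0),
                  neuac = c(0, 0), neugc = c(0, 0)),
    constraints = "none"
  )
  expect_equal(nrow(zero), 1L)
  expect_true(all(zero == 0))

  space <- enumerate_compositions()
  expect_gt(nrow(space), 0)
  ## brute-force re-check of every default constraint
  sia <- space$neuac + space$neugc
  mannose <- space$hexnac == 2
  expect_true(all(space$fuc[mannose] == 0 & sia[mannose] == 0 &
                  space$hex[mannose] >= 5 & space$hex[mannose] <= 9))
  expect_true(all(sia[!mannose] <= pmax(space$hexnac[!mannose] - 2, 0)))
  ## counts inside bounds and lexicographic order
  expect_true(all(space$hexnac >= 2 & space$hexnac <= 8))
  expect_true(!is.unsorted(space$hexnac))
  key <- space$hexnac * 1e8 + space$hex * 1e6 + space$fuc * 1e4 +
    space$neuac * 1e2 + space$neugc
  expect_true(!is.unsorted(key))
  ## empty constraint-satisfying set is allowed
  none <- enumerate_compositions(
    bounds = list(hexnac = c(2, 2), hex = c(3, 3), fuc = c(1, 1),
                  neuac = c(0, 0), neugc = c(0, 0))
  )
  expect_equal(nrow(none), 0L)
  expect_error(enumerate_compositions(bounds = list(
    hexnac = c(3, 2), hex = c(3, 3), fuc = c(0, 0), neuac = c(0, 0),
    neugc = c(0, 0))), "min <= max")
})

test_that("the theoretical glycopeptide table covers sequons with additive masses", {
  s <- "GGGKDNGSHVDKAAAK"   # one sequon at position 6 on peptide DNGSHVDK
  tab <- build_glycopeptide_table(
    s, "trypsin", max_missed = 0,
    bounds = list(hexnac = c(2, 3), hex = c(3, 6), fuc = c(0, 1),
                  neuac = c(0, 1), neugc = c(0, 0))
  )
  expect_true(all(tab$site == 6))
  expect_true(all(tab$peptide == "DNGSHVDK"))
  glyc <- tab[rowSums(tab[c("hexnac", "hex", "fuc", "neuac", "neugc")]) > 0, ]
  expect_equal(glyc$mass,
               peptide_mass("DNGSHVDK") + glycan_mass(glyc),
               tolerance = 1e-9)
  ## unglycosylated row present exactly once with the bare peptide mass
  bare <- tab[rowSums(tab[c("hexnac", "hex", "fuc", "neuac", "neugc")]) == 0, ]
  expect_equal(nrow(bare), 1L)
  expect_equal(bare$mass, peptide_mass("DNGSHVDK"))

  tsv <- tempfile(fileext = ".tsv")
  write_glycopeptide_table(tab, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$mass, tab$mass, tolerance = 1e-9)
})

test_that("FASTA round-trip preserves sequences and description ids", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1 synthetic test protein", "MKNGSAAK",
               ">prot2", "GGNAT"), fa)
  seqs <- read_fasta(fa)
  expect_equal(unname(seqs), c("MKNGSAAK", "GGNAT"))
  expect_equal(names(seqs), c("prot1 synthetic test protein", "prot2"))
  expect_error(read_fasta(tempfile()), "not found")
})
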