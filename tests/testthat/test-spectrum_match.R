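# Peak-list I/O, ppm matching and per-site quantification.

## small theoretical table with composition columns and distinct masses
toy_table <- function() {
  comps <- rbind(
    glycan_composition(hexnac = 2, hex = 5),
    glycan_composition(hexnac = 4, hex = 5, fuc = 1, neuac = 2),
    glycan_composition(hexnac = 4, hex = 5, fuc = 1, neuac = 1)
  )
  data.frame(
    peptide = "NGSK", start = 1L, end = 4L, missed_cleavages = 0L,
    site = 1L, n_sequons = 1L, comps,
    mass = glycopeptide_mass("NGSK", comps),
    stringsAsFactors = FALSE
  )
}

test_that("peak lists round-trip through delimited text", {
  pl <- peaklist(c(1348.476401, 2431.882), c(100, 55.5), source = "digestA")
  path <- tempfile(fileext = ".tsv")
  write_peaklist(pl, path, params = list(seed = 7, note = "fixture"))
  back <- read_peaklist(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$mass, pl$mass, tolerance = 1e-6)
  expect_equal(back$intensity, pl$intensity, tolerance = 1e-9)

  csv <- tempfile(fileext = ".csv")
  write_peaklist(pl, csv)
  expect_equal(read_peaklist(csv)$mass, pl$mass, tolerance = 1e-6)
})

test_that("malformed peak-list rows are rejected with their line numbers", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("mass\tintensity", "1200.5\t10", "oops\t3", "1300.1\t4"), path)
  expect_error(read_peaklist(path), "line\\(s\\) 3")
  writeLines(c("# only a comment"), path)
  expect_error(read_peaklist(path), "no parsable rows")
  expect_error(read_peaklist(tempfile()), "not found")
  expect_error(peaklist(c(-1, 2), c(1, 1)), "finite and > 0")
})

test_that("peaks match within tolerance to the smallest-ppm candidate", {
  tab <- toy_table()
  man5_mass <- tab$mass[tab$hexnac == 2]
  ## 0.00004 Da off a ~1881 Da mass is ~0.02 ppm: a confident match
  res <- match_peaks(peaklist(man5_mass + 0.00004, 10), tab, tol_ppm = 10)
  expect_equal(nrow(res$matches), 1L)
  expect_equal(res$matches$hexnac, 2)
  expect_lt(abs(res$matches$ppm_error), 0.05)
  expect_false(res$matches$ambiguous)
  expect_equal(nrow(res$unmatched), 0L)

  ## ~66 ppm away: unmatched at 10 ppm
  far <- match_peaks(peaklist(man5_mass + 0.125, 10), tab, tol_ppm = 10)
  expect_null(far$matches)
  expect_equal(nrow(far$unmatched), 1L)

  ## empty inputs
  expect_null(match_peaks(peaklist(numeric(0), numeric(0)), tab)$matches)
  none <- match_peaks(peaklist(1500, 1), tab[0, ], tol_ppm = 10)
  expect_equal(nrow(none$unmatched), 1L)
  expect_error(match_peaks(peaklist(1500, 1), tab, tol_ppm = 0), "positive")
})

test_that("assignment equals the brute-force all-pairs scan", {
  set.seed(91)
  for (rep in 1:20) {
    n_tab <- sample(20:60, 1)
    comps <- random_compositions(n_tab)
    tab <- data.frame(
      peptide = "NGSK", site = 1L, n_sequons = 1L, comps,
      mass = runif(n_tab, 800, 4000), stringsAsFactors = FALSE
    )
    n_pk <- sample(10:40, 1)
    from_tab <- sample(n_tab, n_pk, replace = TRUE)
    ppm_shift <- runif(n_pk, -25, 25)
    masses <- tab$mass[from_tab] * (1 + ppm_shift * 1e-6)
    pl <- peaklist(masses, runif(n_pk, 1, 100))
    tol <- sample(c(5, 10, 20), 1)

    res <- match_peaks(pl, tab, tol_ppm = tol)
    oracle <- brute_force_match(pl, tab, tol)

    hit <- !is.na(oracle$chosen)
    expect_equal(if (is.null(res$matches)) 0L else nrow(res$matches), sum(hit))
    if (any(hit)) {
      expect_equal(res$matches$mass, tab$mass[oracle$chosen[hit]])
      expect_equal(res$matches$n_candidates, oracle$n_cand[hit])
    }
    expect_equal(res$unmatched$mass, pl$mass[!hit])
  }
})

test_that("matching conserves peaks and is monotone in tolerance", {
  set.seed(92)
  tab <- toy_table()
  pl <- peaklist(runif(50, 1800, 2600), runif(50, 1, 10))
  prev <- -1L
  for (tol in c(2, 5, 10, 20, 50, 200)) {
    res <- match_peaks(pl, tab, tol_ppm = tol)
    n_matched <- if (is.null(res$matches)) 0L else nrow(res$matches)
    expect_equal(n_matched + nrow(res$unmatched), nrow(pl))
    expect_gte(n_matched, prev)   # tightening never gains matches
    prev <- n_matched
  }
})

test_that("quantification groups by site and honours the combine mode", {
  comps <- rbind(
    glycan_composition(hexnac = 4, hex = 5, neuac = 1),  # Sia
    glycan_composition(hexnac = 4, hex = 5),             # Gal
    glycan_composition(hexnac = 3, hex = 3)              # GlcNAc
  )
  one <- cbind(data.frame(site = 67L, source = "trypsin",
                          intensity = c(70, 20, 10)), comps)
  pro <- quantify_profiles(one, combine = "pooled")
  expect_length(pro, 1L)
  expect_equal(pro[["site 67"]]$proportions[["TerminalSia"]], 0.7)

  ## identical matches from two digests pool to the same proportions
  two <- rbind(one, transform(one, source = "chymotrypsin"))
  pooled <- quantify_profiles(two, combine = "pooled")
  expect_equal(pooled[["site 67"]]$proportions,
               pro[["site 67"]]$proportions, tolerance = 1e-12)
  per <- quantify_profiles(two, combine = "per_digest")
  expect_length(per, 2L)

  ## bare-peptide matches on multi-sequon peptides are excluded but counted
  multi <- rbind(one, cbind(data.frame(site = NA_integer_, source = "trypsin",
                                       intensity = 5), glycan_composition()))
  pro2 <- quantify_profiles(multi, combine = "pooled")
  expect_equal(attr(pro2, "excluded_multi_sequon"), 1L)
  expect_length(pro2, 1L)
  expect_length(quantify_profiles(one[0, ], combine = "pooled"), 0L)
})

test_that("report files are complete and byte-identical across reruns", {
  tab <- toy_table()
  pl <- peaklist(c(tab$mass + 1e-5, 999.9), c(30, 50, 20, 7),
                 source = "trypsin")
  res <- match_peaks(pl, tab, tol_ppm = 10)
  pro <- quantify_profiles(res$matches)
  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  f1 <- render_report(pro, res, d1)
  f2 <- render_report(pro, res, d2)
  for (k in names(f1)) {
    expect_true(file.exists(f1[[k]]))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
  sites <- read.delim(f1[["sites"]])
  expect_true(all(c("site", "kind", "name", "percent") %in% names(sites)))
  expect_equal(sum(sites$percent[sites$kind == "category"]), 100,
               tolerance = 0.2)
  un <- read.delim(f1[["unmatched"]])
  expect_equal(un$mass, 999.9)

  ## empty matches still produce a header-only glycoform table
  empty <- match_peaks(peaklist(999.9, 1), tab, tol_ppm = 5)
  d3 <- file.path(tempdir(), "rep3")
  f3 <- render_report(quantify_profiles(empty$matches), empty, d3)
  expect_equal(length(readLines(f3[["glycoforms"]])), 1L)
})
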