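Package: glycoprofiler
Title: Site-Specific N-Glycopeptide Profiling and 1:1 Binding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for site-specific N-glycosylation profiling of recombinant
    glycoproteins from deconvoluted mass spectra, and for kinetic analysis of
    biolayer-interferometry sensorgrams. Enumerates theoretical glycopeptide
    monoisotopic masses from in-silico protease digests and bounded glycan
    composition spaces, matches deconvoluted neutral-mass peak lists within a
    ppm tolerance, classifies glycoforms (terminal sialic acid, terminal
    galactose, terminal GlcNAc, high mannose, LacNAc repeats) and reports
    per-site glycoform proportions. Globally fits the 1:1 Langmuir binding
    model (shared kon, koff, Rmax) across analyte concentrations and derives
    KD = koff/kon. Includes a seed-deterministic synthetic-data generator for
    glycoproteins, peak lists, sensorgrams and perfusion-culture time series,
    plus a small calculator for cell-specific productivity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
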