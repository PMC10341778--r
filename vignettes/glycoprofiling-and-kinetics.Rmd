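---
title: "Site-specific glycoprofiling and 1:1 binding kinetics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific glycoprofiling and 1:1 binding kinetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoprofiler)
```

This vignette documents the models, parameter choices and numerical
decisions behind `glycoprofiler`, and states plainly what the synthetic
round-trip experiments do and do not demonstrate.

## The glycopeptide identification model

A glycoprotein digested with trypsin (cleavage after K/R), chymotrypsin
(after F/W/Y/L by default) or both yields peptides, some of which carry an
N-glycosylation sequon (N-X-S/T, X ≠ P). In a deconvoluted mass spectrum —
neutral monoisotopic masses with charge states already merged — each
glycopeptide appears as a peak at

`mass = peptide mass + sum of monosaccharide residue masses`,

with residue masses HexNAc 203.079373, Hex 162.052824, Fuc 146.057909,
NeuAc 291.095417 and NeuGc 307.090331 Da (glycosidic condensation already
encoded). Peptide masses are sums of monoisotopic residue masses plus one
water (18.010565 Da) and fixed modification shifts; carbamidomethylation of
cysteine (+57.021464 Da) is always applied because samples are alkylated
with iodoacetamide before digestion. Variable modifications are
deliberately excluded by default: they multiply the search space and the
data this pipeline targets are purified single proteins.

The theoretical table (`build_glycopeptide_table()`) attaches every
enumerated glycan composition to every sequon-covering peptide with up to
`max_missed = 2` missed cleavages. The default composition space —
HexNAc 2–8, Hex 3–12, Fuc 0–2, NeuAc 0–4, NeuGc 0–2, with oligomannose
glycans restricted to HexNAc2/Hex5–9 and at most one sialic acid per
antenna (antennae ≈ HexNAc − 2) — holds 1775 compositions, spanning
paucimannose through tetra-antennary, doubly fucosylated, fully sialylated
complex glycans including N-acetyllactosamine extensions. All bounds and
the constraint predicate are configurable.

## Matching and its tunable parameters

`match_peaks()` assigns a peak to a table entry when
|observed − theoretical| / theoretical ≤ `tol_ppm` × 10⁻⁶, choosing the
candidate with the smallest absolute ppm error. Ties are broken by fewest
distinct monosaccharide types (a parsimony preference among near-isobaric
stacks), then lower theoretical mass; every peak with more than one
in-tolerance candidate is flagged `ambiguous` with the candidate count so
that downstream consumers can see exactly where mass-only identification is
under-determined.

* `tol_ppm` (default 10): suits high-resolution Orbitrap-class data with
  low-ppm calibration. The synthetic round trip uses 20 ppm because its
  simulated mass error SD is 5 ppm and a tolerance of four standard
  deviations keeps essentially every true peak matchable; a tolerance at
  2σ would silently drop ~5 % of true peaks and bias proportions.
* `max_missed` (default 2): the usual compromise between table size and
  coverage of incompletely cleaved peptides.
* Chymotrypsin specificity (default F/W/Y/L, proline-protected): the
  common low-specificity rule without methionine; the residue set is an
  argument because published rules differ on L and M.

Quantification (`quantify_profiles()`) groups matched intensities by sequon
site and normalizes within the site, either pooled across digests (default)
or per digest. Unglycosylated peptide matches count in the denominator —
site occupancy is part of the profile — but bare peptides spanning more
than one sequon are excluded from normalization and reported separately,
because their signal cannot be attributed to a single site without double
counting.

## Glycan categories

Each composition receives exactly one primary category, by precedence:

1. all-zero → `Unglycosylated`;
2. HexNAc2 with ≥ 5 hexoses → `HighMannose`;
3. any sialic acid (NeuAc or NeuGc) → `TerminalSia`;
4. more than three hexoses → `TerminalGal` (≥ 1 galactose beyond the three
   core mannoses);
5. otherwise → `TerminalGlcNAc`.

The precedence (sialic acid before galactose before GlcNAc) makes the
categories mutually exclusive for mixed-terminal glycans: a glycan with one
sialylated and one exposed-galactose antenna counts as sialylated,
consistent with reporting that does not distinguish how many sialic acids a
glycan carries. "Galactose count" is operationalized as hex − 3, assuming
the three core mannoses of complex-type glycans. Orthogonal properties are
flags, not categories: `fucosylated` (≥ 1 Fuc), `contains_neu5gc` (≥ 1
NeuGc) and `lacnac_repeat` (> 6 HexNAc and > 4 galactoses, the
N-acetyllactosamine-extension signature). LacNAc is a flag because extended
glycans are almost always also sialylated; making it a category would
remove them from the sialylation summary. Hybrid glycans are not a separate
category; the terminal-residue rules place them by their exposed termini.

## The 1:1 binding model

Biolayer interferometry sensorgrams are fitted with the 1:1 Langmuir
model. During association at analyte concentration C,

R(t) = Rmax · C/(C + KD) · (1 − exp(−(kon·C + koff)·t)),

the closed-form solution of dR/dt = kon·C·(Rmax − R) − koff·R from R(0)=0;
during dissociation R decays single-exponentially with rate koff from the
response at association end (continuity is enforced, so both phases
constrain the shared parameters). `bli_global_fit()` estimates kon, koff
and Rmax jointly across all concentrations by Levenberg–Marquardt least
squares, with a per-curve additive offset (default on) absorbing residual
baseline after reference subtraction. KD = koff/kon by construction.

Numerical choices: rate constants are optimized as log10 values within
kon ∈ [10², 10⁸] /(M·s) and koff ∈ [10⁻⁷, 1] /s — generous brackets for
antibody–antigen kinetics that keep the optimizer away from zero and
infinity; koff = 0 data therefore fit to the lower bound. Initialization is
data-driven: koff from a log-linear regression on the dissociation decay,
per-curve observed rates k_obs from the log-linear approach to plateau, and
kon from the slope of k_obs against concentration; Rmax from the
highest-concentration amplitude corrected by the initial KD. "No specific
binding" is declared when the fitted Rmax is below 3× the residual noise
SD (configurable) or the fit fails to converge — vendor software reports
such channels without rate constants, and a threshold of a few noise SDs is
the natural operationalization.

## Productivity metrics

For a semi-continuous perfusion culture with a complete daily medium
exchange, each harvest titer is one day's secreted product, so the
cell-specific productivity is simply qP = titer / VCD (µg/mL per 10⁶
cells/mL = pg/cell/day). This end-of-day estimator is preferred over an
integral-of-viable-cells denominator because daily counts and full
exchanges make the ratio exact up to intra-day growth. Cumulative product
per mL is the plain sum of daily titers. `process_summary()` reports both
the post-shift ("production") and pre-shift mean qP so that fold changes
can be computed on either definition.

## What the synthetic generator emulates

`synth_ground_truth()` bundles a random glycoprotein with exactly five
planted sequons (each on a tryptic peptide of 5–25 residues), per-site
glycoform distributions, and noise parameters. The default
`sialylated_heavy` style draws each site's terminal-sialic-acid mass
uniformly in [0.7, 1.0] and splits the remainder Dirichlet-style over
terminal-galactose, terminal-GlcNAc, high-mannose and unglycosylated
categories — the profile shape of a heavily sialylated CHO-produced
glycoprotein. Peak lists perturb theoretical masses with iid Gaussian ppm
error (default SD 5 ppm), intensities with lognormal noise (default CV 1 %)
and add 10 % low-intensity contaminant peaks at uniform random masses.
Sensorgrams are the 1:1 model over five concentrations from 10 to 600 nM
with 600 s association and dissociation phases plus iid Gaussian noise
(default SD 1 % of Rmax). The culture generator produces logistic growth to
~40·10⁶ cells/mL slowed after a day-3 temperature shift, with qP stepping
from 0.1 to 0.5 pg/cell/day. These noise models are the simplest defensible
choices; every parameter is an argument, and all generators are
seed-deterministic down to the written file bytes.

The generator does **not** emulate: isotopic envelopes or deconvolution
artefacts, chromatographic elution, systematic (as opposed to iid) mass
calibration error, mass-transport limitation or heterogeneous-ligand
binding, or metabolite dynamics. Problem sizes are desk-scale by design: a
300-residue backbone with five sites and ~10 glycoforms per site, three
digests, and 5 × ~600-point sensorgrams, so the entire test suite and the
acceptance script run in seconds.

## A known identifiability limit

Mass-only peak assignment has a fundamental limit that users of this
pipeline should understand. With iid 5 ppm mass errors, the observed mass
of a ~3500 Da glycopeptide is uncertain by ~0.018 Da (SD), while the
theoretical table — 1775 compositions on each of several sequon-covering
peptides per site — places roughly ten candidate masses per Dalton.
Cross-peptide near-isobars are therefore common: a peak's nearest table
entry is frequently a glycoform of a *different* site's peptide, and no
per-peak decision rule can recover the truth, because the competing
candidates come from equally plausible peptide families (a backbone-support
parsimony pass was evaluated during development and rejected: majority
voting snowballs onto large families, and weighting cannot separate
families of equal size). In real workflows this ambiguity is resolved by
MS/MS fragmentation or manual annotation, both outside this package's
scope; `run_demo()` computes and prints the resulting site-assignment
accuracy and per-site proportion errors honestly, and the `ambiguous` flag
plus the co-candidate count in every match row shows exactly which
assignments are under-determined. With mass errors at the ~1 ppm level, or
with a composition space restricted to the glycoforms actually expected,
the ambiguity largely disappears — the zero-noise round trip in the test
suite inverts the pipeline exactly.

## Reproducibility

Every stochastic function takes an explicit `seed` and restores the
caller's RNG state, so library calls never perturb a session's random
stream. Reports and generated files are byte-stable for a fixed seed and
configuration; matching is deterministic with documented tie-breaks.
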