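# glycoprofiler

Site-specific N-glycosylation profiling of recombinant glycoproteins from
deconvoluted mass spectra, and 1:1 binding-kinetics analysis of
biolayer-interferometry (BLI) sensorgrams.

Recombinant glycoproteins produced in CHO cells — for example soluble
antigen constructs used to evaluate CAR-T cell binding — carry N-glycans at
N-X-S/T sequons (X ≠ P), and the per-site glycoform distribution is a
critical quality attribute. This package is for analysts who have (a)
deconvoluted neutral-mass peak lists from LC-ESI-MS of protease-digested
glycoprotein and want per-site glycoform profiles, and (b)
multi-concentration BLI sensorgrams and want globally fitted rate
constants.

## What it computes

**Glycopeptide identification and quantification.** Peptides from in-silico
digestion (trypsin: after K/R; chymotrypsin: after F/W/Y/L; both: union of
sites; proline-protected; 0–`max_missed` missed cleavages) are combined
with an enumerated glycan composition space over (HexNAc, Hex, Fuc, NeuAc,
NeuGc) to give theoretical neutral monoisotopic masses

    m(peptide, glycan) = Σ residue masses + 18.010565 + Σ fixed mods
                       + n_HexNAc·203.079373 + n_Hex·162.052824
                       + n_Fuc·146.057909 + n_NeuAc·291.095417
                       + n_NeuGc·307.090331

Observed peaks match within a ppm tolerance (smallest |ppm| wins; ties are
flagged ambiguous with candidate counts). Matched intensities are
aggregated per sequon site into category proportions — Terminal Sia,
Terminal Gal, Terminal GlcNAc, High Mannose, Unglycosylated — with flags
for fucosylation, Neu5Gc content, and LacNAc repeats (> 6 HexNAc and > 4
galactoses).

**1:1 binding kinetics.** Sensorgrams R(t) at analyte concentrations C are
fitted globally (shared k_on, k_off, R_max; optional per-curve offset) with

    association:   R(t) = R_max·C/(C + K_D) · (1 − e^−(k_on·C + k_off)·t)
    dissociation:  R(t) = R(t_assoc_end) · e^−k_off·(t − t_assoc_end)
    K_D = k_off / k_on

**Productivity metrics.** For perfusion cultures with full daily medium
exchange, qP = titer/VCD (pg/cell/day), plus maxima, post-shift means and
cumulative product.

**Synthetic data.** Seed-deterministic generators for glycoproteins with
planted sequons, ground-truth glycoform distributions, noisy peak lists,
sensorgrams and culture time series make every stage testable end to end.

## Worked example

```r
library(glycoprofiler)

## KD from reported rate constants (an FMC63-class antibody):
bli_kd(kon = 2.06e5, koff = 6.57e-4) * 1e9
#> [1] 3.189320
```

3.19 nM: a low-nanomolar equilibrium dissociation constant, i.e. tight
antigen binding. Fitting simulated noisy sensorgrams at those rates
recovers them:

```r
sg  <- simulate_sensorgrams(kon = 2.06e5, koff = 6.57e-4, rmax = 1,
                            noise_sd = 0.01, seed = 1)
fit <- bli_global_fit(sg)
fit
#> Global 1:1 kinetic fit (5 curves, 3005 points)
#>   kon  = 2.062e+05 1/(M s)
#>   koff = 0.0006578 1/s
#>   Rmax = 0.9985 nm
#>   KD   = 3.19e-09 M (3.19 nM)
#>   residual SSE = 0.3215, converged: TRUE
```

The five simulated curves (10–600 nM analyte, 600 s association + 600 s
dissociation, 1 % Gaussian noise) return the generating constants to a
fraction of a percent. The glycoprofiling arm runs the same way:
`run_demo(seed = 1)` generates a five-site glycoprotein, simulates three
digests' peak lists, matches them against each digest's theoretical table
and prints, per site, the maximal absolute error of the recovered category
proportions, the site-assignment accuracy, and the KD recovery error. See
the methods vignette (`vignettes/glycoprofiling-and-kinetics.Rmd`) for the
models, defaults, and a discussion of the mass-only ambiguity limit that
the demo's accuracy metric quantifies.

For file-based runs, write a flat `key = value` config
(`default_run_config()` documents every field) and call
`run_profile("run.cfg")`; it writes a per-site proportion table, a full
glycoform table with ppm errors, categories and flags, and an
unmatched-peak table.

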