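---
title: "Methods: surface-proteome hydropathy, phenotype assays, and stress-tolerance PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-proteome hydropathy, phenotype assays, and stress-tolerance PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probioprofile)
```

This vignette documents the models, parameter choices, and numerical
conventions behind `probioprofile`, and what its synthetic-data tests do and
do not establish about real data.

## The scientific setting

Candidate probiotic lactic acid bacteria are screened on two fronts: the
molecular inventory they expose at the cell surface (which mediates
adhesion, coaggregation with pathogens, and biofilm formation) and their
phenotypic performance under gastrointestinal stress. The package implements
the quantitative core of such a screen: a heuristic surface-proteome
classifier with Kyte–Doolittle hydropathy profiling, the standard plate
assay calculators, and a PCA that ranks isolates by joint stress-tolerance
and antagonism performance.

## GRAVY and hydropathy windows

GRAVY is the arithmetic mean of per-residue Kyte–Doolittle values; negative
values indicate hydrophilic chains. Two conventions matter and are fixed
here:

* **Ambiguity codes.** X/B/Z and selenocysteine (U) carry no hydropathy
  value. They are excluded from both numerator and denominator rather than
  scored as 0, because scoring them 0 would bias X-rich draft annotations
  toward the middle of the scale. The count of scored residues is reported
  (`n_scored`) so heavily masked sequences are visible.
* **Stops.** A single trailing `*` is stripped on input; an internal `*` is
  a validation error. Silently accepting truncated ORFs would corrupt
  GRAVY without a trace.

The mature-chain GRAVY of a secreted protein is the GRAVY of the residues
after the signal-peptide cleavage site. Since signal peptides are strongly
hydrophobic, mature GRAVY is almost always below full-chain GRAVY; the
exact condition (mean hydropathy of the cleaved leader above the whole-chain
mean) is asserted as an algebraic identity in the tests.

## The surface classifier

Three sequence features define the surface subset, with precedence
LPXTG-anchored > lipoprotein > secreted (the categories are mutually
exclusive; anchoring is the most specific evidence):

1. **Secretion signal**: a window of `h_window` residues starting within the
   first `sp_scan_len` positions with mean hydropathy ≥ `h_thresh`, followed
   by an A-X-A triplet whose second alanine (the cleavage position) lies in
   `[max(sp_cleave_min, h_end + 1), sp_cleave_max]`. First qualifying window,
   then first qualifying triplet — a deterministic tie-break.
2. **Lipobox**: the first L(A/S)(A/G)C match whose cysteine lies in
   `[lipobox_c_min, lipobox_c_max]`, with a qualifying hydrophobic window
   ending before the cysteine. A full cleavage-site call is deliberately not
   required: lipoprotein signal peptides end in the lipobox itself, so
   demanding an additional A-X-A would double-count the motif.
3. **LPXTG anchor**: the last L-P-x-T-G match starting within the final
   `lpxtg_c_window` residues (closest to the C-terminus, where sortase
   acts), followed strictly after the motif by a transmembrane window
   (`tm_window` residues at mean hydropathy ≥ `h_thresh`) and a tail of
   `tail_len` residues containing at least `tail_min_kr` lysines/arginines.

The defaults (`sp_scan_len` 45, `h_window` 8, `h_thresh` 1.5, cleavage in
15–45, lipobox Cys in 15–40, `lpxtg_c_window` 50, `tm_window` 15, tail 10
with ≥ 2 K/R) are sized for canonical Gram-positive architecture: signal
peptides of ~20–35 residues with an h-region of at least 8 hydrophobic
residues, and sortase anchors ~30–40 residues from the C-terminus. They are
heuristics, not calibrated probabilities, and all of them are exposed via
`classifier_params()` and a flat key:value config file
(`inst/extdata/benchmark-params.conf`) so a real proteome's published
surface counts can be approached by tuning. An initial methionine is not
required, since annotated proteomes contain alternative starts.

`gravy_benchmark()` computes the four headline statistics of a profiled
proteome (whole-proteome median GRAVY, surface-subset median, percentage of
surface proteins with GRAVY < 0, and the secreted mature-chain median) for
exactly this benchmarking use.

## Group statistics

Welch's *t*-test (unequal variances, Satterthwaite df) and the Mann–Whitney
*U* test are both run, two-sided, on every comparison: surface vs whole
proteome, surface vs non-surface background, and — for secreted proteins —
mature vs full GRAVY. The mature-vs-full comparison summarises two value
sets of the same *n*; no paired test is claimed for it. Quartiles use linear
interpolation between order statistics (R's default type 7), documented
because interquartile ranges are part of the reported summaries. The *U*
test is exact by full enumeration when `min(n) ≤ 8` with no ties, and
otherwise uses the normal approximation with tie and continuity corrections;
the tests verify the approximation stays within 0.02 of the exact value at
the boundary. No multiple-testing correction is applied across the three
comparisons. Degenerate inputs follow explicit conventions: two constant
groups with equal means give *p* = 1 (no evidence either way), with unequal
means an error.

## Assay calculators

The biofilm class uses the printed inclusive bounds: Negative ODt ≤ ODc,
Weak ODc < ODt ≤ 2·ODc, Moderate 2·ODc < ODt ≤ 4·ODc, Strong ODt > 4·ODc.
Replicates are averaged before classification; SDs are carried for reporting
only. All percentage metrics are exact arithmetic on their inputs, and
negative values (e.g. negative adhesion to toluene, meaning OD gain in the
aqueous phase of a strongly hydrophilic surface) are reported as-is, never
clamped.

## Stress-tolerance PCA

Δlog CFU endpoints per stressor (acid, bile, lysozyme) are converted to
retention fractions 10^Δlog — the surviving cell fraction — and combined
with mean antagonism halo diameters (mm) into an isolate × 4 matrix. The
endpoints (sampling times, pH levels) are taken as inputs rather than fixed
by the package, since protocols vary. Columns are Z-scored with the
**population** SD convention (divisor *n*), matching common PCA
preprocessing defaults; the sample convention is available via `sd_type`.
A constant column is an error, not a silent NaN.

PCA is the SVD of the column-centered matrix; explained-variance ratios are
eigenvalue shares. Two numerical conventions make results reproducible:
each component is oriented so its largest-magnitude loading is positive
(biplot axes are otherwise sign-ambiguous), and ratios below 1e-12 are
reported as exactly 0 — with three isolates the third and fourth components
are numerically null. The tests assert the full algebra: orthonormal
loadings, reconstruction of the centered matrix to 1e-9, the
`min(n_isolates − 1, n_variables)` rank bound, and row-permutation
invariance.

## The synthetic-data generators

The generators produce data with the statistical structure the analysis
assumes, with ground truth attached, so every stage is testable offline.

**Proteomes.** Residues are drawn from an average bacterial composition
exponentially tilted so the expected Kyte–Doolittle mean hits the target:
`p_i(β) ∝ p_i · exp(β · KD_i)`, with β solved by `uniroot` (the expectation
is strictly increasing in β). The default background target is −0.18; the
mature regions of planted surface proteins are tilted to the background
target plus `surface_gravy_shift` (default −0.03). Because soluble cytosolic
proteins rarely carry long N-terminal hydrophobic runs (such chains would
engage the membrane-insertion machinery), the N-terminal scan region of
background proteins is drawn from a composition tilted to `nterm_hydropathy`
(default −0.8, typical of charged N-termini), with the rest of the chain
solved per protein so the whole-chain expectation still hits the background
target. Under an untilted i.i.d. draw the signal-peptide heuristic fires on
a background protein far more often than it does on real proteomes; the
hydrophilic N-terminus restores a realistic background call rate (~3%).

Planted constructs are built to the classifier's documented definitions
(hydrophobic stretch from {L, I, V, F}, motif positions randomized within
their legal ranges so the position gates are exercised) and validated
against the classifier at generation time; if a random segment accidentally
spawns a higher-precedence motif the protein is redrawn from the seeded
stream, and generation fails loudly if validation cannot be met. Detector
recall on planted truth is therefore 1 by construction — a consistency
check of generator and classifier, not evidence about real sequences.
Defaults: 3000 proteins, planted fractions 6% secreted, 0.05% lipoprotein,
0.1% LPXTG (counts rounded), lengths ~ N(300, 120²) truncated at 60.

What the generator does **not** emulate: real signal-peptide diversity
(cleavage sites other than A-X-A), domain structure and composition
autocorrelation, pseudogenes and frameshifts, and annotation noise. Passing
recovery tests therefore demonstrates internal consistency and statistical
calibration, not field performance of the heuristics on arbitrary genomes.

**Plates and panels.** Biofilm plates draw replicate ODs around
class-consistent means (Moderate targets 3 × ODc) and reject noise levels
that would flip the class with probability > 1%; since "Negative" sits on
the inclusive ODt ≤ ODc boundary, it is only generable noise-free. Stress
panels place non-dominant isolates around a base Δlog of −0.5 (~32%
survival) with halos near 13 mm (inhibition-zone scale typical of LAB
overlay assays); a designated dominant isolate is constructed to hold the
strictly best value in all four variables, the configuration in which PC1
should carry almost all variance and point at the dominant isolate — which
is exactly what the PCA property tests assert.

## Problem sizes and determinism

Every generator is a pure function of its spec and seed (`withr::with_seed`;
repeated runs are byte-identical, asserted in the tests). The shipped test
suite runs the classifier recovery at the full 3000-protein scale, the
detection-power study at 100 seeds × 3000 proteins, the test-size simulation
at 1000 null replicates, and the enumeration cross-checks over the complete
small-sample grid — a few minutes end to end on one CPU.

## Known limitations

* The heuristic classifier is intentionally simple; it has no probabilistic
  model of cleavage sites and will not match dedicated predictors on real
  proteomes without tuning.
* Exact reproduction of any particular published surface count depends on
  the (unpublished) thresholds behind that count; the benchmark config is a
  starting point, not a calibration.
* The Mann–Whitney exact path covers `min(n) ≤ 8` without ties; larger or
  tied samples use the corrected normal approximation.
* With three isolates the PCA is rank-2: PC2 loadings are determined by a
  single residual direction and should not be over-interpreted.
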