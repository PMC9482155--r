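---
title: "Methods: window-based DMR discovery and three-state methylation panel evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based DMR discovery and three-state methylation panel evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urometh)
```

`urometh` implements the computational pipeline behind an 8-marker urine
DNA methylation test for bladder cancer: discovery of differentially
methylated regions (DMRs) from cell-line bisulfite methylation calls,
per-marker decision-threshold calibration, three-state panel scoring, and
diagnostic-accuracy evaluation. This vignette documents the models, the
parameters that matter, the numerical conventions, and the choices made
where the design was genuinely open.

## Coordinates and input formats

All internal coordinates are 0-based, half-open. Conversions happen only
at I/O boundaries: bismark-style coverage files and GFF3 are 1-based
inclusive, BED is 0-based half-open. CpGs are keyed by the cytosine
position only; duplicate records for the same position (as produced by
strand-split methylation extractors) are merged by summing counts rather
than rejected. The per-CpG methylation level ("beta") is
`n_meth / (n_meth + n_unmeth)`.

## Window-based DMR discovery

The discovery input is one methylation call table per cell line, split
into a *target* group (the cancer of interest) and an *off-target* group
(other urological cancers), typically 8 vs 8 lines. Each chromosome is
tiled at two scales, 200 bp and 1000 bp. Scanning conventions:

* **Tiling, not sliding, by default.** `step` defaults to the window size.
  Tiling is deterministic and the two scales already overlap each other;
  smaller steps are supported via `window_config(step =)`.
* **Every sample must qualify.** A window is emitted only if *every*
  sample has at least `min_cpgs_per_window` (default 4) CpGs with coverage
  at least `min_coverage_per_cpg` (default 10) inside it. This prevents
  group means computed over different sample subsets.
* **Unweighted means.** The per-sample window beta is the unweighted mean
  of that sample's qualifying CpG betas (pooling counts instead would let
  high-coverage CpGs dominate), and group means are unweighted means over
  samples.

A window is kept when at least `min_target_fraction` (default 0.75) of
target samples reach window beta `min_target_beta` (default 0.4) *and* at
most `max_offtarget_fraction` (default 0, i.e. none) of off-target samples
exceed `max_offtarget_beta` (default 0.1). These four thresholds are
exposed rather than hard-coded because reasonable pipelines differ here;
the defaults demand near-unanimous silence in the off-target group, which
is what a methylation biomarker needs for specificity.

Retained windows that overlap by at least 1 bp on the same chromosome are
unioned into one candidate (interval merging is delegated to
`IRanges::reduce` with `min.gapwidth = 0`); abutting half-open intervals
do **not** merge. Candidates are annotated with the distance to the
nearest transcription start site: 0 if a TSS lies inside the interval,
otherwise the gap to the nearest edge, with *distal* meaning strictly
greater than 1500 bp. TSSs are strand-resolved (feature start on `+`, last
base on `-`); features without strand are rejected because their TSS is
undefined.

## Per-marker ROC analysis and threshold calibration

Marker values are methylated-copy concentrations (ddPCR-style, arbitrary
but consistent units). The AUC is the Mann–Whitney statistic normalized by
`n_case × n_control` with ties counted ½, and its p-value is the
two-sided Wilcoxon rank-sum test — the significance test matches the
estimator. When all values are identical the AUC is 0.5 with p = 1.

Threshold calibration searches the midpoints between consecutive distinct
pooled values, plus one cut below the minimum and one at the maximum. A
sample is positive when its value is **strictly greater** than the
threshold (ties are negative; the rule must be fixed for
reproducibility). Among cuts whose specificity is **strictly above** the
floor (default 0.95), the one maximizing sensitivity wins; ties break
toward higher specificity, then higher threshold. Strictness has a
concrete small-sample consequence: with 20 controls, 19/20 = 0.95 fails
"> 0.95", so no false positive is tolerated. Calibration controls default
to healthy controls only; other-cancer controls are kept for evaluation.
Because the top cut (at the pooled maximum) always has specificity 1, a
valid threshold always exists — possibly with sensitivity 0, which is
returned as such rather than hidden.

The downstream marker-selection filter keeps markers with calibration
sensitivity strictly above 0.5 and AUC p-value below 0.05.

## Three-state panel scoring

With thresholds fixed, each patient gets `n` binary marker calls. The
panel outcome is NEGATIVE at 0 methylated markers, POSITIVE at
`k` or more (default `k = 2` of 8), INCONCLUSIVE in the band `1..k−1`.
Missing marker calls are handled conservatively: the outcome is POSITIVE
if the observed positives already reach `k`, and otherwise INCONCLUSIVE —
NEGATIVE is never issued with a missing call, because only a certainly
all-negative panel should spare a cystoscopy.

`cutoff_search()` evaluates every `k` from 1 to `n`, computing sensitivity
and specificity over conclusive samples and the conclusive rate. The
recommended `k` maximizes Youden's J times the conclusive rate. That
utility is an explicit stand-in for an informal "best combination of
sensitivity, specificity and conclusive results" criterion; the full table
is always returned so callers can apply their own rule. On synthetic
discovery cohorts the recommendation oscillates between `k = 1` and
`k = 2` across seeds: the calibrated thresholds make single false-positive
markers rare in simulated controls, so the inconclusive band buys less
than it does in noisier real data. This is a property of the generator,
not of the scoring rule.

`panel_fit()` packages calibration plus rule into a fitted S3 object with
`print`, `summary`, `coef` (the thresholds) and `predict` (scores a new
cohort) methods.

## Diagnostic evaluation

Inconclusive patients are excluded from the confusion counts; sensitivity
`tp/(tp+fn)` and specificity `tn/(tn+fp)` are therefore *conclusive-only*
quantities, reported with exact Clopper–Pearson 95% intervals
(`stats::binom.test`). Degenerate cells (no conclusive cases, say) yield
`NA`, never 0. Two quantities need care:

* **Spared cystoscopies** is `tn / n_total` — true negatives among *all*
  tested patients, because inconclusive patients still undergo cystoscopy.
* **Predictive values** come from Bayes' formula at an assumed population
  prevalence (default 0.20 for gross-hematuria patients), never from the
  cohort's own column totals, since evaluation series are case-enriched.
  With sensitivity 82/89, specificity 154/165 and prevalence 0.20 the
  formula gives NPV 97.94% and PPV 77.55%; published figures for the same
  inputs round the PPV to 77.5% and print an NPV of 98.1% that the
  standard formula does not reproduce — `urometh` reports the formula
  value and does not attempt to reverse-engineer the difference.

Stratified sensitivity recounts `tp/(tp+fn)` per tumor stage or grade
among conclusive cases, reporting how many cases lacked a stratum label.
The age-dependence check splits cases into two equally sized groups at the
median age (ties to the younger group) and runs a two-sided rank-sum test
per marker; with fewer than 4 cases it declares itself underpowered
instead of reporting unstable p-values.

## What the synthetic generators emulate

**RRBS simulator.** Shared CpG positions (a gap mixture producing
island-like clusters, mean gap 150 bp), negative-binomial coverage (mean
100, dispersion 8 — RRBS libraries at around 100× coverage), and a
locus-specific baseline beta drawn from a two-mode mixture (modes 0.05 and
0.85, 70% low) shared across samples, around which each sample draws
beta-binomial counts (precision 30). This puts the genome-wide mean
methylation near 35%, typical of RRBS. Planted DMRs are non-overlapping
intervals (default six of 500 bp / 12 CpGs) where the two groups receive
different baselines (0.85 vs 0.03). Identical seeds give byte-identical
coverage files.

**Urine cohort simulator.** A two-part model per patient × marker: a
latent binary *methylated signal* state, then a concentration. For cases,
the state probability is `plogis(a_j + u_i)` with a patient-level normal
shedding factor `u_i` (SD 2.0 on the logit scale) and the intercept `a_j`
calibrated by Gauss–Hermite quadrature so the *marginal* positivity equals
the configured per-marker sensitivity (defaults 0.54–0.73). Controls get
the same construction with a background-methylation factor (SD 3.0)
calibrated to `1 − specificity` (defaults 0.95–0.96 against healthy
controls; other-cancer controls carry a false-positive odds multiplier of
2, landing their effective specificity around 0.91–0.98). Positive case
markers draw log-normal concentrations (meanlog 3 + 0.25·`u_i`, sdlog
0.8), positive control markers a lower log-normal (meanlog 0.5, sdlog
0.6), and negative markers are 85% exact zeros with occasional trace
background (meanlog −1.5). Stage and grade are sampled from a
hematuria-like case mix and are independent of shedding by default (an
optional `stage_shedding_delta` links higher stage to higher shedding).

The shedding SDs are the one genuinely free knob. They were set by
numerical integration of the logit-normal model — not by fitting data — so
that the 2-of-8 rule attains a conclusive-only cohort sensitivity near
0.93 with the default marker sensitivities (the case value 2.0), and so
that control false positives concentrate in few patients, keeping the
control inconclusive rate near 8% (the control value 3.0). This is the
mechanism that makes the panel's sensitivity (≈ 0.92–0.96) exceed every
single marker's (0.54–0.73) while marker calls stay positively correlated
within patients: without correlation, eight markers at these marginals
would push panel sensitivity implausibly close to 1.

What the generator does *not* emulate: droplet-level ddPCR artifacts
(droplet calling is upstream of this package), assay-specific background
differences between markers, urine DNA input variation, batch effects, and
any dependence of marker specificity on benign urological disease.
Passing tests on this generator therefore demonstrate correctness of the
*computations* and internal consistency of the model — not clinical
performance on real urine.

## Numerical conventions and degenerate inputs

* Strict inequalities throughout: positivity is `value > threshold`,
  specificity must exceed the floor strictly, distality is `distance >
  1500`, marker selection needs sensitivity `> 0.5`.
* Empty samples, empty groups, unknown labels, negative counts and
  missing strands are errors with informative messages, not silent
  repairs; undefined rates are `NA`, never 0.
* All randomness flows from explicit integer seeds in the config objects;
  the pipeline derives stage seeds from one master seed and manifests
  md5 checksums of every artifact.

## Problem sizes used by the test suite

The suite exercises oracle comparisons on 1,000 random interval sets
(n ≤ 12), AUC instances up to 200 values, calibration instances up to 500
values, brute-force window recomputation on a 10-kb locus, planted-DMR
recovery pooled over 20 simulator seeds (recall and precision ≥ 0.95),
and marker-sensitivity recovery on cohorts of 2,000 patients. These sizes
keep the full suite under a minute while leaving the asymptotic behavior
to the same code paths used at scale.

## Known limitations

* The window filter thresholds are package defaults, not estimates; real
  discovery runs should tune them to their cell-line panel.
* The cutoff-search utility is one defensible choice among several; use
  the returned table for alternatives.
* Predictive values assume a single fixed prevalence; no uncertainty is
  propagated into PPV/NPV.
* The simulators are calibrated to marginal rates and one correlation
  mechanism; they make no claim to reproduce joint distributions of real
  urine ddPCR panels.
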