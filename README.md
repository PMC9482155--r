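# urometh

Tools for building and evaluating **urine DNA methylation biomarker panels**
for bladder cancer triage.

Patients presenting with gross hematuria are currently sent to cystoscopy,
an invasive procedure that comes back negative for most of them. A urine
test that can safely rule bladder cancer out would spare a large fraction
of those cystoscopies. One established design for such a test is an
8-marker DNA methylation panel read out by droplet digital PCR: each marker
is scored methylated or not against a calibrated concentration threshold,
and the panel result is **negative** (0/8 methylated markers),
**inconclusive** (1/8) or **positive** (≥ 2/8). Only a fully negative test
spares cystoscopy; positive and inconclusive patients proceed to it.

`urometh` implements the full computational path of that design:

1. **DMR discovery** — tile per-CpG bisulfite methylation call tables
   (bismark-coverage format) from target-cancer vs off-target cell lines
   with 200-bp and 1000-bp windows; keep windows where ≥ 75% of target
   samples have window-mean beta ≥ 0.4 while no off-target sample exceeds
   0.1; merge overlapping windows into candidates and annotate distance to
   the nearest TSS (distal if > 1500 bp).
2. **Marker calibration** — per-marker ROC analysis with the Mann–Whitney
   AUC (`AUC = U / (n₁n₀)`, ties ½) and threshold selection: among cuts
   with specificity **strictly above 95%** on healthy controls, pick the
   one maximizing sensitivity.
3. **Panel scoring** — strict `value > threshold` marker calls and the
   three-state rule above, plus a search over positivity cutoffs
   `k = 1..8` reporting sensitivity, specificity and conclusive rate per
   `k`.
4. **Diagnostic evaluation** — sensitivity/specificity over conclusive
   results with exact (Clopper–Pearson) 95% CIs, predictive values from
   Bayes' formula at an assumed prevalence (20% for hematuria patients),
   `PPV = sens·π / (sens·π + (1−spec)(1−π))`, the spared-cystoscopy rate
   (true negatives over all tested patients), and stage/grade-stratified
   sensitivity.
5. **Synthetic data** — seeded generators for cell-line RRBS profiles with
   planted DMRs and for urine cohorts in which a latent log-normal
   *tumor-shedding* factor drives all marker positivities jointly, so the
   whole pipeline runs and is tested without any external download.

## Worked example

Calibrate a panel on a simulated discovery cohort (112 samples: 26 cases,
56 healthy and 30 other-urological-cancer controls) and evaluate it on an
independent simulated hematuria cohort (273 patients, 93 with confirmed
bladder cancer):

```r
library(urometh)

disc <- simulate_urine_cohort(urine_sim_config(preset = "discovery", seed = 1))
fit  <- panel_fit(disc$cohort)          # thresholds + 2-of-8 rule
fit
#> <urometh_panel> 8-marker panel, positive at >= 2 methylated
#>   calibrated on 112 samples (specificity floor 0.95, controls: control_healthy)

ev    <- simulate_urine_cohort(urine_sim_config(preset = "hematuria", seed = 8))
calls <- predict(fit, ev$cohort)
diagnostic_summary(calls$outcome, ev$cohort$group == "case", prevalence = 0.20)
#> Conclusive patients  93.8% (256/273)
#> Sensitivity          94.1% (80/85), 95% CI 86.8%-98.1%
#> Specificity          98.2% (168/171), 95% CI 95.0%-99.6%
#> PPV                  93.1% (at prevalence 20%)
#> NPV                  98.5% (at prevalence 20%)
#> Spared cystoscopies  61.5% (168/273)
```

Reading the output: 256 of the 273 patients got a conclusive (0/8 or ≥ 2/8)
result; among conclusive cases 80 of 85 were detected; 168 of the 273
patients were true negatives and would have been spared a cystoscopy. The
predictive values are computed from sensitivity, specificity and the
assumed 20% prevalence, not from the cohort's own case fraction (the
simulated series is case-enriched at 34%).

`coef(fit)` returns the calibrated per-marker thresholds and
`summary(fit)` adds per-marker calibration sensitivity/specificity, AUC
and rank-sum p-values. `run_pipeline(pipeline_config(seed = 1))` chains
every stage — RRBS simulation, window discovery, calibration, scoring,
evaluation — and writes all artifacts plus a checksummed manifest; a thin
command-line wrapper lives at `inst/cli/urometh.R`.

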