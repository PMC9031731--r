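# qeegsync

Quantitative EEG analysis of amnestic mild cognitive impairment (aMCI)
subtypes. The package implements, as a tested and reusable pipeline, the
two global spectral measures used to characterize synaptic dysfunction in
resting-state EEG —

* **Global field power (GFP)** — at each frequency, the root mean square of
  spectral amplitudes across all electrodes,
  `GFP(f) = sqrt(mean_k |c_k(f)|^2)`, a reference-free index of generalized
  signal strength in µV;
* **Global field synchronization (GFS)** — at each frequency, the
  normalized eigenvalue difference `(λ1 − λ2)/(λ1 + λ2)` of the 2×2
  origin-anchored scatter matrix of the per-channel (Re, Im) Fourier
  coefficients: 1 when all channels share a single phase, ~0.27 at the
  21-channel chance level for independent channels;

— together with the statistics used to compare single-domain (sd-aMCI) and
multidomain (md-aMCI) patient groups: pooled-variance t-tests with
`η² = t²/(t² + df)` effect sizes (recomputable directly from published
mean/SD/n summaries), Mann-Whitney routing via a normality screen,
chi-square tests, ANCOVA with age as covariate, mixed-type
Pearson/point-biserial correlation matrices, and a class-balanced random
forest (5,000 trees, 3 variables per split, per-tree 70% subsampling
without replacement with equal counts from both classes) reporting
out-of-bag error and permutation variable importance.

Because the underlying clinical recordings are not public, the package
ships two simulators that make every stage testable end to end: a
21-channel EEG generator with a tunable globally phase-locked component per
frequency band (known ground-truth synchronization), and a two-group cohort
generator whose margins reproduce the published group summary statistics.

Intended users: clinical neurophysiology and biomarker researchers who want
GFP/GFS and the accompanying group analysis as scriptable, reproducible
building blocks.

## Worked example

```r
library(qeegsync)

# 1. Effect size from published summary statistics (mean, SD, n per group)
age <- pooled_t_from_summary(summary_stats(66.85, 7.31, 52),
                             summary_stats(63.13, 7.12, 30), "age")
print(age)
#> <group_comparison> age: pooled_t, stat = 2.241, df = 80, p = 0.02783, eta_squared = 0.05905

# 2. Synthetic 21-channel EEG -> band-level GFP/GFS features
rec <- simulate_eeg(eeg_sim_spec(duration = 60, seed = 1))
rec <- apply_average_reference(rec)
ft  <- features_for_subject(spectra(epoch_and_screen(rec, 100)))
print(ft)
#> <qeeg_features> sim (30 epochs)
#>      delta  theta  alpha   beta
#> GFP 1.2211 0.8138 1.6157 0.4479
#> GFS 0.4339 0.4245 0.6096 0.3576

# 3. Table-calibrated synthetic cohort -> balanced random forest
cohort <- simulate_cohort(cohort_sim_spec(seed = 1))
model <- fit_balanced_forest(
  cohort,
  predictors = c("age","sex","education","mmse","csf_abeta42","csf_ptau",
                 "csf_ttau","csf_ng","gfp_delta","gfp_theta","gfp_alpha",
                 "gfp_beta","gfs_delta","gfs_theta","gfs_alpha","gfs_beta"),
  outcome = "group", cfg = rf_config(n_trees = 1000, seed = 2))
print(oob_report(model))
#> <rf_report> OOB error 30.5% (1000 trees)
#>   per-class error: sd-aMCI 28.8%, md-aMCI 33.3%
#>   1 tied vote(s) broken to class sd-aMCI
head(permutation_importance(model), 5)
#>   predictor importance rank
#> 1 gfs_delta   0.012000    1
#> 2      mmse   0.009000    2
#> 3 education   0.005375    3
#> 4 gfs_theta   0.005125    4
#> 5 gfp_alpha   0.003075    5
```

Reading the output: the recomputed age comparison gives a small-to-medium
effect (η² = 0.059, p = 0.028, sd-group older). The simulated recording's
alpha band carries the strongest common component (defaults are
alpha-dominant eyes-closed EEG), so alpha GFS (0.61) sits well above the
21-channel chance level (~0.28) while the weakly synchronized beta band
sits near it. On the cohort drawn from the published group summaries the
balanced forest classifies clearly below the 50% chance level, with
slow-band global synchronization (GFS delta/theta) among the top-ranked
predictors — lower values pointing to the single-domain group, the same
direction the clinical study reported.

The full pipeline (recordings → features; cohort → statistics → forest →
hashed manifest) runs from one call or from the thin CLI wrapper:

```r
run_pipeline(run_config(mode = "simulate", out_dir = "out", seed = 1))
```

```sh
Rscript inst/scripts/qeeg.R --mode simulate --out out --seed 1 --trees 1000
```

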