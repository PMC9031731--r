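---
title: "Global field power and synchronization analysis of resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global field power and synchronization analysis of resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegsync)
```

## The measures and the model

Resting-state EEG in cognitive impairment is commonly summarized by two
global, reference-independent spectral measures computed on common
average-referenced 2-second epochs.

**Global field power (GFP).** At one frequency bin, GFP is the root mean
square of the spectral amplitudes across the $K$ electrodes,
$\mathrm{GFP}(f) = \sqrt{\tfrac{1}{K}\sum_k |c_k(f)|^2}$, a single number
per frequency summarizing generalized signal strength. With this package's
Fourier scaling the units are microvolts of equivalent sinusoid amplitude.

**Global field synchronization (GFS).** At one frequency, the complex
Fourier coefficients of the $K$ channels form a cloud of points
$(\mathrm{Re}\,c_k, \mathrm{Im}\,c_k)$ in the plane. If every channel's
activity at that frequency shares one phase (up to real, possibly negative,
per-channel gains), the cloud is collinear through the origin. With
$\lambda_1 \ge \lambda_2 \ge 0$ the eigenvalues of the $2\times 2$
origin-anchored scatter matrix $M^\top M$,
$$\mathrm{GFS}(f) = \frac{\lambda_1 - \lambda_2}{\lambda_1 + \lambda_2}
\in [0, 1],$$
which is 1 for a single common phase, 0 for a perfectly isotropic cloud,
and invariant to multiplying all coefficients by any nonzero complex scalar
(global amplitude and phase). GFS is therefore a measure of how much of the
multichannel activity a single phase can explain — a global functional
coupling index — not a measure of power.

Both curves are computed per epoch, averaged across epochs within a
subject, and then averaged within the conventional frequency bands delta
(1–3.5 Hz), theta (4–7.5 Hz), alpha (8–11.5 Hz), and beta (12–19.5 Hz).
Beta is capped below 20 Hz because higher scalp-EEG frequencies are often
contaminated by muscle activity; the gamma band is not analysed. On the
0.5 Hz grid of 2-second epochs, band averages are unweighted means over
bins with $f_{lo} \le f \le f_{hi}$, endpoints inclusive (delta covers
exactly the six bins 1.0–3.5 Hz). The DC bin is excluded from all band
math.

### Numerical choices

* **Fourier scaling.** One-sided sinusoid-amplitude convention: a
  unit-amplitude bin-centered sinusoid yields coefficient magnitude 1.0.
  Interior bins are scaled by $2/N$, DC by $1/N$, and the Nyquist bin by
  $\sqrt2/N$, so with the default rectangular taper the Parseval identity
  $\sum_{f>0} |c(f)|^2/2 = \widehat{\mathrm{Var}}(x)$ holds to machine
  precision. A Hann taper (corrected by its coherent gain) is available for
  leakage-sensitive work; Parseval then holds only approximately.
* **Eigenvalues in closed form.** The $2\times2$ eigenvalue difference is
  computed as $\sqrt{\mathrm{tr}^2 - 4\det}/\mathrm{tr}$; the test suite
  verifies agreement with a generic symmetric eigensolver to $10^{-12}$
  over 10,000 random inputs.
* **Origin anchoring.** The scatter matrix is not mean-centered: centering
  would break the "common phase through the origin" reading and the
  GFS = 1 identity for gain-scaled common sources. A centered variant is
  available (`center = TRUE`) for sensitivity analysis, and a
  total-power-weighted pooled-across-epochs estimator
  (`gfs_mode = "pooled"`) complements the default per-epoch averaging.
* **Silent frequencies.** GFS is undefined when all coefficients at a bin
  are zero; this raises an error rather than returning an arbitrary value.

### The chance level of GFS

GFS is positively biased at finite channel counts: independent channels
yield an expected value of roughly $0.27$ at $K = 21$ rather than 0.
`gfs_chance()` estimates this chance level by Monte Carlo, drawing either
circular complex-Gaussian coefficients (`"rayleigh"`, the asymptotic
distribution of filtered-noise Fourier coefficients) or unit-amplitude
random phases, optionally with the channel-mean coefficient removed
(`reference = "average"`). The latter matters: average referencing couples
the channels (one degree of freedom is removed), which raises the chance
level slightly, so the oracle should be referenced the same way as the
data it is compared against.

One caveat is documented rather than hidden: the windowed DFT of strictly
band-limited noise has slightly non-circular coefficients at band-edge bins
(spectral leakage), which biases narrow-band chance GFS upward by about
0.01 relative to the circular-Gaussian oracle. The effect is a property of
any windowed GFS estimator on band-limited signals — real narrow-band EEG
rhythms are subject to it too — and is why chance-level tests compare
within standard errors derived from the per-epoch spread (bins within an
epoch are correlated, so a per-bin independence assumption would be
overconfident).

## Preprocessing contract

Recordings (EDF, the package's raw binary fixture format, or in-memory
matrices) are re-referenced to the common average, cut into consecutive
non-overlapping 2-second windows, and screened: a window containing any
sample above ±100 µV (configurable) is dropped with reason `"amplitude"`,
and a window with a zero-variance channel with reason `"flat"`. This
deterministic screen is a testable stand-in for clinical visual artifact
rejection plus ICA-based ocular cleaning; it is *not* equivalent to the
clinical procedure, and no vigilance monitoring is modelled. Epochs do not
overlap. If every epoch is rejected the pipeline stops with an explicit
"no analyzable data" error rather than producing features from nothing.

## What the simulators emulate — and what they do not

### Synthetic EEG

`simulate_eeg()` builds channel $k$ as
$$x_k(t) = g_k \sum_b c_b\, s_b(t) + \sum_b u_b\, n_{kb}(t) + a\, p_k(t),$$
where $s_b$ is one band-limited waveform shared by all channels (white
noise through a 4th-order Butterworth bandpass applied forward and
backward, unit RMS), $n_{kb}$ are independent band-limited noises, $p_k$
is per-channel $1/f$ background, and $g_k$ is the common source's scalp
topography. The common-to-independent power ratio $c_b^2/u_b^2$ is the
ground-truth dial for band GFS: 0 pins GFS at the chance level and
$u_b = 0$ pins it at 1.

The default topography is a random zero-mean, unit-RMS Gaussian vector per
recording. This is deliberate: a constant topography ($g_k \equiv 1$)
makes the common source a common-mode signal that average referencing
cancels almost entirely, silencing the synchronization dial, whereas a
mixed-sign topography emulates the dipolar projection of a cortical source
and survives re-referencing. GFS is invariant to real per-channel gains,
so the identity GFS = 1 for pure common sources is unaffected — a fact the
tests exploit.

Defaults are an alpha-dominant eyes-closed profile (common amplitudes
1.5/1/3/0.5 µV for delta/theta/alpha/beta, independent amplitudes
1.5/1.2/2/1 µV, background 2 µV at exponent 1), 21 channels in the 10/20
montage, 256 Hz sampling (the source recordings' rate is not public;
256 Hz is a common clinical choice and configurable), and 300 s duration —
shorter than a 15–20 min clinical session to keep simulation studies
fast; pass `duration = 900` for session-length records.

Not emulated: ocular/muscle artifacts, sleep or vigilance changes,
volume-conduction geometry, head models, or topographic source structure.
Passing tests on this generator therefore validate the *estimators and
their contracts*, not clinical recording conditions.

### Synthetic cohorts

`simulate_cohort()` draws two groups (defaults n = 52 and n = 30, matching
the published single-domain and multidomain amnestic MCI groups) of 15
variables — demographics, MMSE, four CSF markers, eight band-level
GFP/GFS features — from a Gaussian copula whose margins hit the published
group means and SDs, with sex drawn independently as Bernoulli (52% and
53% women, i.e. 27/52 and 16/30).

Positivity-constrained variables (concentrations, GFP, GFS) use a
0-truncated normal whose parameters are *moment-matched* so the truncated
distribution has exactly the target mean and SD. Naive alternatives fail:
resampling out-of-range draws from an untruncated normal shifts the
t-tau mean upward by ~3.5% (its mass below zero is non-negligible), and
clipping creates a point mass at 0. MMSE is clipped to its 0–30 scale
range — the real instrument has the same ceiling — which shrinks its SD
slightly by design. MMSE is kept continuous rather than integer-rounded to
preserve the published moments.

The inter-variable correlation matrix is a modelling choice (the
patient-level correlations were never published): strong coupling inside
the CSF tau/neurogranin block, moderate coupling within the GFP and GFS
band blocks, weak amyloid–tau, age–tau and slow-GFS–tau links. It is
validated to be symmetric positive definite, and any user-supplied matrix
is checked for the same. Real cohorts are not multivariate normal; group
separation in the simulator is accordingly somewhat easier than in
patients, so forest error rates on synthetic cohorts are read as
direction-of-effect checks (below chance, slow-band GFS highly ranked),
not as reproductions of clinical error rates.

## Group statistics

`pooled_t_from_summary()` recomputes two-group comparisons from published
mean/SD/n triplets: pooled-variance Student t, $df = n_a + n_b - 2$,
two-sided p, and $\eta^2 = t^2/(t^2 + df)$ (0.01 small, 0.06 medium, 0.14
large). The pooled — not Welch — variant is the one that reproduces the
published effect-size/p pairs from the printed tables (e.g. age
$\eta^2 = 0.059$, $p = 0.028$); Welch can be had from `t.test()` directly.
A handful of printed cells (GFS theta, p-tau, and the GFP delta/alpha/beta
effect sizes) cannot be recovered exactly from the rounded table entries;
they are documented expected misses rather than assertion targets.

`compare_groups()` routes raw data: Shapiro–Wilk at $\alpha = 0.05$ per
group (the screen is a declared choice; no particular test was specified
for the original analysis), pooled t if both groups pass, otherwise
Mann–Whitney (exact for small untied samples). Rank-route effect sizes are
reported as the Kruskal–Wallis-based rank $\eta^2_H = (H-1)/(n-2)$ and
flagged as `rank_eta_squared` — deliberately not mixed with the t-based
convention. Categorical variables get a chi-square on the 2×2 table with
$\phi^2$ as the effect size. `ancova_adjusted()` fits the covariate first
and reports the adjusted group F with partial $\eta^2$. p-values are not
multiplicity-adjusted, matching the original reporting; apply `p.adjust()`
downstream if desired. `correlation_matrix()` uses Pearson for
continuous–continuous and point-biserial (Pearson on 0/1 dummies) for
binary variables, coded sd-aMCI = 0 / md-aMCI = 1 and women = 0 / men = 1;
constant columns are flagged as undefined rather than silently zeroed.

## The class-balanced random forest

The classifier follows the published configuration literally:

* 5,000 trees by default (tests and the pipeline scale down to a few
  hundred or 1,000 — the OOB estimate stabilizes well before that at these
  sample sizes);
* each tree trained on 70% of the data drawn **without replacement** — a
  70/30 split per tree, not a bootstrap — with **equal counts from both
  classes**, sized by the minority class: $\lfloor 0.7 \times 30 \rfloor
  = 21$ subjects per class per tree (the 50/50 proportion was specified;
  the absolute count was not, and balancing before the 70% draw is this
  package's documented resolution of that ambiguity);
* `mtry = 3` variables tested per split, kept at the stated 3 even though
  the square-root rule at 16 predictors would give 4 — the stated value
  wins, and `mtry = "sqrt"` exposes the rule;
* unpruned CART with Gini impurity, nodes split until pure with at least
  one observation per node (`min_node_size = 1`).

No installed forest implementation offers this subsampling scheme together
with external OOB bookkeeping, so the CART grower and everything around it
are implemented in the package; an off-the-shelf forest serves as an
independent cross-check on easy data in the test suite. Out-of-bag
classification uses the majority vote over trees where a subject was
out-of-sample; exact vote ties go to class 0 (sd-aMCI) and are flagged in
the report, subjects never out-of-sample are reported as missing rather
than dropped (with thousands of trees this does not occur at n = 82).
Permutation importance is the raw mean decrease in OOB accuracy per
predictor across trees — not rescaled by its standard deviation — ranked
in the report. Hyperparameters are fixed a priori; there is no tuning or
model selection.

## Pipeline and reproducibility

`run_pipeline()` chains the stages (simulate or load recordings →
preprocess → features; simulate or load a cohort → group statistics →
correlation matrix → forest) and writes CSV/JSON outputs plus
`manifest.json` with the package version, seed, config echo and MD5, MD5
hashes of every output, per-stage timings, and per-subject epoch-rejection
tallies (clinical rejection counts were never published, so the manifest
at least makes the synthetic ones explicit). One global seed is fanned out
to per-stage child seeds through a fixed multiplicative-congruential step
(`child_seed()`), so stages can be re-run in isolation. Two runs with the
same config and seed produce byte-identical data outputs; the manifest is
the one file allowed to differ, and only in its timing fields — it still
records identical hashes for everything else. In simulate mode the default
run generates a handful of 60-second recordings across a grid of
synchronization ratios (exercising the EEG path end to end) and an 82-row
cohort from the published tables for the statistics and forest stages;
problem sizes are configurable upward.

EDF export/import is a minimal continuous 16-bit implementation (one 1-s
record per block, common clinical layout); start date/time are fixed
placeholders so identical data export byte-identically. CSF amyloid
positivity uses the strict cutoff: positive iff Aβ42 < 550 ng/L.

## Known limitations

* The artifact screen is far simpler than clinical artifact rejection;
  features from heavily contaminated real recordings will differ from
  clinical qEEG pipelines.
* Narrow-band chance-level GFS carries the small leakage bias described
  above; comparisons against the chance oracle should use the
  average-referenced oracle variant and per-epoch standard errors.
* Synthetic cohorts are Gaussian-copula idealizations; classifier error
  rates on them are optimistic relative to patient data and are used only
  for directional and calibration checks.
* GFS is a global index: no topographic, regional, or source-space
  synchronization is computed, and the gamma band is out of scope.
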