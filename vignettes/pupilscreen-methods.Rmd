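---
title: "Pupillometric screening for ADHD: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupillometric screening for ADHD: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the data model

Task-evoked pupillometry records pupil diameter at high frequency while a
subject performs a cognitive task. During a visuospatial working-memory
task, a probe stimulus presented mid-trial evokes a dilation whose size,
speed and regularity differ between unmedicated children with ADHD and
healthy controls; those differences can be summarized as scalar features
and fed to binary classifiers to produce an objective screening signal.

`pupilscreen` implements that pipeline end to end. The unit of raw data is
a *trial*: one pupil-diameter series on a uniform millisecond grid
(`pupil_trial`), 8 s long at 1 kHz in the reference protocol, with the
probe at 5000 ms. Subjects carry a group label (`ADHD` — the unmedicated
positive class — or `CTRL`) and a list of trials (`pupil_cohort`). Feature
engineering produces a subjects-by-features table (`feature_matrix`),
which is the interface between the time-series half of the package and the
statistics/classification half. Missing samples (blinks, tracker dropouts)
are `NA` internally and empty cells in CSV — never a sentinel number.

## Preprocessing

Three per-trial steps, in a fixed order:

1. **Exclusion.** A trial is dropped when *more than* 80% of its samples
   are missing (strict inequality; exactly 80% survives). Missingness is
   assessed on the raw series, *before* imputation — assessing it after
   imputation would make the criterion vacuous, and the order is otherwise
   underdetermined by the protocol.
2. **Imputation.** Interior gaps are filled with the cubic spline through
   the observed `(t, pupil)` points. We use Forsythe–Malcolm–Moler end
   conditions (`stats::spline(method = "fmm")`), under which any cubic
   polynomial is reproduced exactly regardless of gap placement; natural
   end conditions (zero second derivative at the boundary) were rejected
   because they distort interpolation whenever the underlying curve has
   boundary curvature — measured errors reached ~3e-2 mid-series on a
   plain cubic and grew by orders of magnitude near the ends. Leading and
   trailing missing runs are filled with the nearest observed value first,
   because extrapolating a cubic outside the observed support is
   numerically unstable. Trials with fewer than 4 observed samples are an
   error (the exclusion step should have removed them).
3. **Reduction.** Non-overlapping 16 ms block means, so an 8000-sample
   1 kHz trial becomes exactly 500 samples with a 16 ms period. Block
   means (decimation) rather than a sliding window is the only reading
   that yields 500 outputs from 8000 inputs with a 16 ms window; any
   trailing remainder shorter than a block is discarded, and output
   timestamps are block start times. The reduction preserves the global
   mean exactly when the window divides the length, and reducing twice
   composes multiplicatively (16 ms then 256 ms equals 256 ms once).

All features are computed on the reduced series — reduction exists to make
feature extraction cheap, so extraction runs downstream of it.

## Dilation metrics and the custom catalogue

With origin sample $(T_0, P_0)$, the dilation velocity at sample $i$ is
the secant slope $V_i = (P_i - P_0)/(T_i - T_0)$ (pupil units per ms), the
acceleration is $A_i = (V_i - V_0)/(T_i - T_0)$, and the accumulated
velocity $AV_i$ is the running prefix sum of $V$. Two conventions are
deliberately pinned down and isolated behind single functions:

* $V$ at the origin is undefined and stored as 0;
* $V_0$ in the acceleration formula is the velocity at the *first sample
  after the origin* (the first index where a secant is defined), which
  makes $A$ identically zero on linear series and well defined from three
  samples on.

The 22-item custom catalogue (`extract_custom_features`) summarizes the
trial with windowed extremes/means of pupil size, whole-series moments,
and velocity/accumulated-velocity/acceleration summaries split at the
probe. "Before probe" quantities anchor the origin at the trial start;
"after probe" quantities re-anchor it at the probe sample, so they measure
the stimulus-locked response rather than drift accumulated since trial
start. Windows are millisecond half-open intervals $[T_1, T_2)$ mapped to
0-based sample indices by floor division; on a 16 ms grid the "5000 ms"
probe sample is therefore the sample at 4992 ms. Items 1–3 are read as
windowed extreme *values* (max/min), matching how the group contrast is
described (a larger post-probe maximum for controls), not as counts of
local extrema.

Items 16–19 of the catalogue are printed in a partially garbled form in
the source protocol: item 19 as printed duplicates item 17, and item 18
mixes a mean velocity with an accumulated-velocity maximum. They are
implemented literally (item 18 as `mean velocity after − max accumulated
velocity before`; item 19 as the duplicate), with a documented `item19 =
"velocity_contrast"` switch for the plausible intended reading
(`max velocity after − max accumulated velocity after`). Nothing is
silently "fixed": a downstream consumer comparing against the printed
catalogue gets the printed catalogue.

Moment conventions, shared everywhere in the package: population variance,
skew as the standardized third central moment, kurtosis as excess (Fisher)
kurtosis without bias correction; skew and kurtosis of a constant series
are 0 by convention.

## General time-series features

The general registry reimplements, from their definitions, the
discriminative features the screening study reported, plus the basic
moments (12 entries; 34 columns total with the custom catalogue):

* **Absolute energy** $\sum x_i^2$.
* **Real FFT coefficient** $\mathrm{Re}(X_k)$ of the unnormalized DFT;
  the headline coefficient is $k = 2$.
* **Change-quantile variance**: population variance of $|x_{i+1} - x_i|$
  over consecutive pairs whose *both* endpoints lie inside the corridor
  $[q_{0.4}, q_{0.8}]$ (linear-interpolation sample quantiles, endpoints
  inclusive); 0 when fewer than two pairs qualify.
* **Approximate entropy** (Pincus), embedding $m = 2$ as the protocol
  fixes, tolerance $r = 0.2\,\sigma$ ($\sigma$ the population sd — the
  conventional choice, exposed as `r_factor` because the protocol leaves
  it unstated); self-matches included; a constant series returns 0.
* **Peak count** with support $n = 10$: samples strictly greater than all
  10 neighbours on each side.
* **Standard error of the OLS slope** of the series against its 0-based
  index.

The remaining several hundred features a bulk extraction library would
produce are represented by the registry as an extension point, not
reproduced one for one: they add no testable surface here and track a
moving third-party catalogue. Each registry entry is a pure function from
a trial to one finite number, so per-subject aggregation (per-trial
computation, then the arithmetic mean over the subject's kept trials) is
uniform across custom and general features.

## Univariate statistics

`mann_whitney_u` computes $U_x = \sum \mathrm{rank}(x) - n_x(n_x+1)/2$
with midranks, so $U_x + U_y = n_x n_y$ always. For pooled sizes up to 12
without ties the two-sided p-value is exact, by enumeration of all
$\binom{n}{n_x}$ label assignments ($p = \min(1, 2\min(P(U \le u),
P(U \ge u)))$); beyond that, the normal approximation with tie and
continuity correction. The threshold 12 keeps enumeration instant while
covering the regimes where the approximation is weakest. P-values are
two-sided throughout, and no multiple-testing correction is applied by
default (a Benjamini–Hochberg column is available but off), matching the
descriptive use of the ranking.

`anova_f` is the closed-form two-group one-way ANOVA ($F = MSB/MSW$, df
$(1, n-2)$), which for two groups equals the squared pooled-variance $t$
statistic and induces the same feature ordering as $|t|$ — this is the
standard univariate filter used inside cross-validation folds, vectorized
over feature columns because it sits in the hot path. Degenerate cases are
pinned: zero within-group variance with unequal means gives $F = \infty$,
$p = 0$; a constant feature ranks last with $p = 1$.

## Classifier evaluation

`nested_cv` runs repeated, stratified, nested ten-fold cross-validation.
Per outer fold, using training rows only: ANOVA-F selection of the top 9
features, z-score standardization, stratified 5-fold inner grid search
maximizing the AUROC of pooled inner out-of-fold scores, refit of the
winner, then scoring of the held-out fold. Per-repetition metrics come
from the pooled out-of-fold predictions of that repetition.

Where the protocol is silent, the package makes these choices and flags
them as its own:

* **Repetitions** default to 40 (the protocol range is 30–50); the
  analysis scripts and acceptance checks use 10–30 to stay desk-fast.
* **Aggregate half-width** is the standard error of the per-repetition
  metric over repetitions (`ci = "ci95"` switches to a 95% t-interval) —
  the protocol prints "±" without defining it.
* **Stratified folds**: with a 28/22 (or smaller) class split, plain
  10-fold CV risks single-class folds, which break every metric.
* **Standardization** fitted on training rows only — required by the
  margin- and distance-based families (SVM, KNN, penalized logistic).
* **Decision threshold** 0.5 on the predicted positive-class probability
  for sensitivity/specificity; AUROC uses the scores directly with half
  credit for ties (the rank formulation, identical to $U/(n_1 n_2)$).
* **Hyperparameter grids** are small fixed defaults per family (ridge
  penalty for logistic regression; kernel × cost for the SVM; tree depth;
  $k$ for KNN; `mtry` for the random forest), overridable through
  `classifier_spec`; ties in the inner search resolve to the first grid
  row, so tuning is deterministic given the seed.

Leakage safety is testable, not just asserted: `nested_cv` accepts a
`perturb_test` audit hook that transforms the held-out design matrix
*after* selection, tuning and fitting. Replacing held-out rows with noise
must leave the selected features and tuned hyperparameters bit-identical
(only the metrics may change); the suite runs exactly that check. The
report records per-fold selections and winning hyperparameters to make
the comparison possible.

## The synthetic cohort generator

No clinical recordings ship with the package; `generate_cohort` emulates
the cohort structure the pipeline assumes: 28 + 22 subjects, 160 trials
each, 8 s at 1 kHz, probe at 5000 ms. Each trial is

$$\text{pupil}(t) = b_s + A_s\,(1 - e^{-(t - t_p)/\tau_s})\,[t \ge t_p]
  + \text{decay}(t) + \text{AR}(1)(t) + \varepsilon(t),$$

a saturating-exponential evoked response (chosen over gamma or sigmoid
shapes because its two parameters map directly onto the discriminative
quantities: amplitude → post-probe maximum, time constant → dilation
velocity) that plateaus 2 s after the probe and then decays, on top of a
subject baseline, slow AR(1) noise parameterized by stationary sd and
correlation time (so realizations are comparable across sampling rates),
and white jitter. Blinks arrive as a Poisson process with lognormal
durations; a small per-trial probability produces "catastrophic" trials
missing a contiguous ~85–95% of samples, so the exclusion rule has real
work. Everything derives from one seed; the same seed reproduces the
cohort byte for byte.

Group contrasts encode the qualitative orderings the screening study
reports: controls get a larger amplitude, a shorter rise time constant and
larger slow variability (larger post-probe maximum, faster dilation,
larger sd); the ADHD group gets more high-frequency jitter (higher
approximate entropy, more peaks). Absolute parameter values are the
package's own: the magnitudes were set once so that between-subject
standardized group gaps sit around 1.5–2 and the strong-effect
nested-CV SVM AUROC lands in the 0.85–0.95 regime at the scaled-down
cohort size the tests use, and were then frozen. `effect = "moderate"`
halves every gap; `effect = "null"` gives both groups the control
parameters, which is the ground-truth-free null the permutation checks
complement.

What the generator does *not* emulate — and hence what passing tests do
not show about clinical data: biophysical pupil dynamics, luminance
confounds, task-performance structure (correct/incorrect trials),
age/sex composition, and any realistic covariance between features beyond
what the additive model induces. A strong AUROC on the synthetic cohort
validates the machinery (no leakage, correct arithmetic, sane
calibration), not clinical performance.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on a
scaled-down cohort: 14 ADHD / 11 control subjects, 6 trials each, 8 s
trials at 250 Hz — the 16 ms reduction window then spans 4 samples and the
reduced series keeps its 500-sample structure, so every window constant
downstream is exercised unchanged. Statistical checks (permutation null,
biomarker-recovery replicates) use 20–30 replications. These sizes are the
package's chosen operating point for its own verification; the generator's
defaults remain the full-scale cohort.

A fixed permutation of a small label vector is *not* a valid null — it
retains chance correlation with the true groups, and on a strong-effect
cohort that residual correlation alone yields AUROC well above 0.5. The
permutation-null checks therefore draw a fresh permutation per repetition,
the standard construction.

Other numerical conventions worth knowing: feature-matrix CSVs are written
with 17 significant digits so round trips are bit-faithful at double
precision; RadViz min-max normalizes each feature column (a constant
column is an error naming the feature, and an all-zero normalized row is
placed at the origin); the RadViz anchor order follows the requested
feature order, and the projection is invariant under per-feature affine
rescaling because the normalization absorbs it.

## Known limitations

* Sensitivity/specificity at the fixed 0.5 threshold are unstable at
  25–50 subjects; AUROC is the robust summary, and the per-repetition
  tables are serialized so downstream users can re-aggregate.
* The exact Mann–Whitney path covers only untied pooled samples up to 12;
  midrank ties always route to the corrected normal approximation, which
  is approximate for very small tied samples.
* Item 19 of the custom catalogue duplicates item 17 under the literal
  reading (see above); column 19 carries no independent information unless
  the interpretation switch is flipped.
* The registry's general features are a curated subset; analyses that
  depend on the long tail of a bulk extraction catalogue need additional
  registry entries.
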