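---
title: "Methods: multimodal SVM detection of early cognitive impairment in Parkinson's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal SVM detection of early cognitive impairment in Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcog)
```

## The problem

Roughly half of Parkinson's disease (PD) patients develop dementia within a
decade, and the transition is preceded by a mild-cognitive-impairment stage
that routine screening often misses. `pdcog` implements a classification
pipeline that separates PD patients with beginning cognitive deficits
(PD-CD, Montreal Cognitive Assessment score 16–21) from cognitively
unimpaired patients (PD-ND, MoCA ≥ 24) using three feature modalities:

* **GMV** — atlas-based gray-matter volumes (130 regions plus total
  intracranial volume as a covariate),
* **FC** — inter-network functional connectivity: Fisher-z-transformed
  Pearson correlations between the mean signals of 17 large-scale cortical
  networks from band-pass-filtered resting-state time series,
* **clinical** — six routine parameters (age, sex, Hoehn & Yahr stage,
  UPDRS III, levodopa equivalent daily dose, disease duration).

Borderline MoCA scores (22–23) and dementia-range scores (< 16) are
excluded; `assign_groups()` is the total mapping over integer scores 0–30.
The positive class throughout is PD-CD.

The package operates on *parcellated* signals and *tabulated* volumes.
Image-space preprocessing (segmentation, registration, smoothing, nuisance
regression, atlas application) is out of scope: those stages require
scanner-space images, while every computation defined on their outputs —
means, correlations, classifiers, covariate-adjusted tests — is
implemented and tested here.

## Connectivity features

For each subject the pipeline discards the first 3 volumes (scanner
equilibration), applies a band-pass filter, and computes all pairwise
Pearson correlations of the network signals. With $P = 17$ networks this
yields $P(P-1)/2 = 136$ unique pairs, ordered row-major over the upper
triangle in atlas label order so that feature names (`"DMN-2~VIS-2"`) are
stable. Correlations are variance-stabilized with Fisher's transform
$z = \operatorname{artanh}(r)$.

Numerical choices:

* **Filter realization.** An order-4 Butterworth band-pass (0.01–0.1 Hz)
  applied forward and backward (`signal::filtfilt`), i.e. zero-phase, so
  filtering cannot introduce lags that would distort inter-network
  correlations. Columns are demeaned first; a constant input maps exactly
  to zero. The high edge must stay below the Nyquist frequency
  $1/(2\,\mathrm{TR})$ (≈ 0.281 Hz at TR = 1.78 s).
* **Clipping.** $|r| = 1$ would give infinite $z$; `fisher_z()` clamps to
  $\pm(1 - 10^{-7})$, so $z(1) \approx 8.406$. The constant is documented
  and tested.
* **Degenerate inputs.** A zero-variance network signal is an error naming
  the network; discarding all volumes is an error.

## Scenario tables and normalization

Three scenarios are assembled (clinical features always included): GMV
(130 + 6 = 136 features), FC (136 + 6 = 142) and GMV+FC (272). Sex is
binary encoded (0 = female, 1 = male) before normalization; MoCA defines
the label and is never a feature; TIV is carried as a covariate only.
Hoehn & Yahr half-steps are treated as numeric — they enter a z-score
transform, which presumes an interval scale; this is a documented
simplification. Missing values are rejected, not imputed.

`zscore_normalize()` has two modes. The default `"global"` mode
standardizes each feature over *all* subjects, matching the original
analysis; it emits a message because global statistics leak test-fold
information into training. The `"per_training_fold"` mode defers scaling
to the evaluators, which then estimate means and SDs on each training
fold and apply them to the held-out fold. The difference between the two
protocols is quantified by `leakage_experiment()` (below).

## Bootstrap greedy feature ranking

`rank_features()` runs $B$ iterations (default 1000; the desk-scale
default in `pdcog_config()` is 200). Each iteration:

1. draws a with-replacement bootstrap resample of subjects (stratified
   retry if a class is missing, bounded at `max_redraws`),
2. walks a fresh random permutation of the feature pool,
3. scores each candidate addition by the mean per-fold ROC-AUC of a
   linear SVM (C = 1) over a stratified 5-fold CV of the resample,
4. accepts a candidate only if it *strictly* increases the best AUC so
   far, removing it from the pool; every feature is considered at most
   once per iteration.

Selection counts over iterations give the ranking; ties break by
ascending feature name so results are platform-independent. The top-k
list (default 50) feeds the subset search.

Design decisions where the procedure was genuinely open:

* **What "bootstrap" resamples.** Whether subjects are resampled or only
  the feature order is randomized is ambiguous; both readings are
  implemented (`resample_subjects`, default `TRUE` — the standard meaning
  of bootstrap, and the one that lets selection frequencies reflect
  sampling variability).
* **The first feature.** An empty model has no AUC; the empty set is
  credited with chance level 0.5 (`accept_first_above`), so the first
  feature must beat chance. This makes the baseline explicit rather than
  accepting the first candidate unconditionally.
* **Inner CV.** One stratified 5-fold split per iteration, reused for
  every candidate within the iteration, so comparisons along the greedy
  path are paired. Folds whose training part is single-class contribute
  `NA` and drop out of the mean.

## Exhaustive subset search

`subset_search()` evaluates **every** subset of the ranked candidates up
to `max_size` (enumeration is lexicographic; $\binom{50}{6} = 15{,}890{,}700$
at full scale, which is why the original cap is six features) against a
65-point hyperparameter grid: linear kernel with
$C \in \{0.01, 0.1, 1, 10, 100\}$; RBF adds
$\gamma \in \{10^{-3}, 10^{-2}, 10^{-1}, \text{scale}\}$; polynomial adds
degree $\in \{2, 3\}$. `"scale"` resolves per training fold to
$1/(p \cdot \operatorname{var}(X_{\text{train}}))$, the conventional
meaning of the keyword.

Evaluation uses repeated stratified k-fold CV (default 10 × 10; desk
scale 10 × 3). Fold assignments are drawn once per seed and shared across
*all* subsets and grid points, so every model comparison is paired and
the argmax is not driven by fold noise. Metrics (accuracy, precision,
recall, F1 from per-fold confusion counts with the usual 0-denominator
conventions; ROC-AUC as the mean of per-fold AUCs from decision scores)
are averaged over folds × repeats. The best model per size maximizes mean
accuracy, with a total tie order: higher mean ROC-AUC, then lexicographic
subset order, then grid order. Parallelization is over subsets and cannot
change the result; a checkpoint file per subset-size block lets long
searches resume.

The grid search shares the folds used for reporting (hyperparameters are
not re-chosen inside each training fold); that matches the source
protocol and carries the optimistic bias discussed below.

### Performance note

The search and the ranker fit hundreds of thousands of SVMs on ~38
subjects. The package trains through the compiled libsvm routine that
`e1071` ships, via a minimal dense binary C-classification entry point,
and reconstructs decision values from the returned support vectors —
identical results to `e1071::svm()` + `predict()` (asserted exactly in
the test suite) at a fraction of the per-call overhead. One full
desk-scale scenario (B = 200 ranking on 272 features plus a
top-15/size-3/65-config/30-fold search) runs in about a minute on one
core.

## Univariate ANCOVA

`run_group_stats()` supplements the multivariate models with a classical
per-feature analysis of covariance: `value ~ group + covariates`, where
covariates are age and sex for FC features, plus TIV for GMV features.
The group effect is the 1-df F test
$F = (\mathrm{RSS}_{\text{reduced}} - \mathrm{RSS}_{\text{full}}) /
(\mathrm{RSS}_{\text{full}} / \mathrm{df}_{\text{res}})$, identical to
the squared pooled t statistic when no covariates are present. Under the
default dimensions this yields 266 rows (130 GMV + 136 FC). The reported
direction is the sign of the adjusted group coefficient (PD-CD minus
PD-ND).

Benjamini–Hochberg adjustment (`stats::p.adjust`) is applied **per
modality family** by default, because the two families are tested under
different covariate sets; a pooled family over all 266 features is
available (`fdr_family = "pooled"`). The choice is recorded in the output
attributes. Note that re-applying BH to already-adjusted values is *not*
a no-op — adjusted values are not p-values; the package never does so.

## The synthetic cohort generator

`generate_cohort()` emulates the study's data structure so that every
downstream stage is testable without patient data:

* **Clinical table.** Independent truncated Gaussians / categorical draws
  per group matching the reported cohort statistics (e.g. age
  68.75 ± 6.56 vs 65.39 ± 6.17 years; Hoehn & Yahr tallies; LEDD;
  MoCA drawn inside 16–21 / 24–30 so the label assignment reproduces the
  intended groups). No cross-correlation between clinical variables is
  imposed — none is reported, and inventing one would plant structure the
  tests would then "discover".
* **GMV.** Region-wise Gaussians (baseline means 2–14 ml, SD = 12% of the
  mean, scaled by `noise_sd`); a planted effect shifts the impaired
  group's mean by `d` SD units of the control distribution (positive =
  larger in PD-CD). TIV is drawn with a sex offset.
* **Time series.** White Gaussian noise, band-limited by the same
  0.01–0.1 Hz zero-phase filter the pipeline applies downstream (so the
  planted signal survives refiltering), standardized, and mixed through
  the Cholesky factor of the group's target correlation matrix. The
  baseline matrix is block-structured (within-family correlation 0.3,
  between 0.05); planted `fc_effects` add a delta to chosen pairs for the
  impaired group. Non-positive-definite targets, self-pairs and deltas
  implying $|r| \ge 1$ are errors naming the offending pair.
* **Determinism.** One master seed; per-subject and per-stage streams are
  derived deterministically, so identical parameters reproduce the cohort
  element for element.

Default planted effects are calibrated to the reported group F
statistics: for a 1-df contrast $d = \sqrt{F (n_1+n_2)/(n_1 n_2)}$, and a
correlation difference follows from the sampling SD of a subject's
Fisher z under a band-limited series, $\mathrm{sd}(z) \approx
1/\sqrt{N_\mathrm{eff}-3}$ with $N_\mathrm{eff} = 2 \cdot \mathrm{BW}
\cdot T \cdot \mathrm{TR}$ effective observations
(`calibrate_fc_effect()`). At the default acquisition (200 retained
volumes, TR 1.78 s, 0.09 Hz bandwidth) $N_\mathrm{eff} \approx 64$, so a
subject's sample correlation is a noisy estimate — exactly the
within-group variance that makes recovery non-trivial at n = 38.

What the generator does **not** emulate: head motion and physiological
noise, spatial structure within networks/regions, inter-feature
correlations (age–atrophy coupling, GMV–TIV scaling), non-Gaussian tails,
and site effects. Passing tests therefore demonstrate that the
*computational pipeline* recovers planted structure under realistic
sampling noise — not that the classifier generalizes on real patients.

## Known behaviors worth understanding

* **Sampling variability dominates at n = 38.** A planted 0.8-SD region
  effect realizes in one 38-subject cohort with SD ≈ 0.33, so any
  single-cohort check of "is the planted feature ranked highly" is a
  coin flip for moderate effects. The recovery tests aggregate selection
  counts over five replicate cohorts and rank within modality-specific
  scenarios (mirroring the per-scenario feature reduction of the source
  protocol).
* **Selection optimism.** On effect-free cohorts the unnested
  protocol (global normalization, ranking and exhaustive search on all
  subjects, best CV accuracy) reports ~0.75 accuracy where truth is 0.5;
  wrapping normalization, ranking, search and model choice inside outer
  training folds (`leakage_experiment()`) returns estimates distributed
  around 0.5. This reproduces, as a measured property, the optimism
  caveat the source analysis itself acknowledges. The null experiment
  uses a linear-only grid and a reduced cohort (20 regions, 6 networks)
  to keep it cheap; the contrast is qualitative and large.
* **Band-limiting inflates correlation sampling noise.** The effective
  sample size of a band-limited series is ~2·BW·duration, about a third
  of the raw volume count; tests of moment recovery use series long
  enough that the entrywise tolerance holds with margin.

## Problem sizes used by the tests and acceptance script

Full-scale settings (B = 1000, top-50, subsets to size 6, 10 × 10 CV) are
supported and config-gated behind the printed cost estimate. The shipped
tests and `scripts/acceptance.R` run the pipeline at desk scale, chosen
so the whole suite completes in minutes on one core while keeping every
structural constant at study scale: 38-subject cohorts, 130 regions, 17
networks, 203 volumes; B = 200 and top-15 candidates with subsets to
size 3 under 10-fold × 3-repeat CV for recovery; 30–50 replicate null
cohorts for calibration; 6 replicates for the leakage contrast.

## Limitations

The package analyzes parcellated derivatives, not images; it implements
one feature-selection family (bootstrapped greedy forward selection) and
one classifier family (SVM); the nuisance-regression step of resting-state
preprocessing is not represented in the generator; and the clinical
sampling model is independent-marginals. These bounds are inherited from
the source protocol's scope and from what tabulated statistics can pin
down.
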