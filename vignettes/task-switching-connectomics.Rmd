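---
title: "Task-based connectomics of cued task-switching: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based connectomics of cued task-switching: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(switchconn)
```

## The analysis problem

Cognitive flexibility — the ability to disengage from one task set and engage
another — is commonly probed with cued task-switching: on every trial a cue
(a full word such as "SHAPE" or a single letter such as "S") instructs one of
two judgements on the upcoming stimulus, and trials where the cued task
differs from the previous trial's task are *switch* trials. In case-control
fMRI studies of this paradigm, the question is whether the *pattern* of
task-related functional connectivity (FC) across the whole brain separates
patients from controls, and whether any difference is driven by altered
network integration and segregation.

`switchconn` implements that analysis end to end for two-group designs:

1. **Single-trial amplitudes.** Each region's time series is decomposed into
   per-trial response amplitudes with the least-squares-separate (LSS) GLM.
2. **Beta-series connectivity.** Pearson correlation of trial-to-trial
   amplitude variability between all region pairs, per subject, restricted
   to one trial condition (switch trials by default).
3. **Connectome classification.** F-score feature ranking plus a linear
   max-margin classifier under leave-one-out cross-validation (LOOCV), with
   a feature-count sweep and a label-permutation significance test.
4. **Network efficiency.** Weighted global and local efficiency across a
   sparsity-threshold sweep, summarised per subject by the area under the
   curve (AUC) and compared between groups with pooled-variance t-tests.

A seeded synthetic-data generator produces designs, trial-wise responses and
BOLD-like series with known ground truth, so every stage is testable without
imaging data.

## Single-trial estimation

The LSS scheme fits one ordinary-least-squares GLM per trial. Events are
modelled as zero-duration sticks at cue onset convolved with the canonical
double-gamma haemodynamic response. Each trial's design matrix has exactly
two task regressors — the trial of interest, and all remaining trials
combined — plus the six rigid-body motion parameters, mean white-matter and
CSF signals, and an intercept (11 columns with the standard confound set).
The trial-of-interest coefficient, collected over trials, is the subject's
beta series.

Choices worth knowing about:

* **HRF parameters** (`hrf_model()`): peak delay 6 s, undershoot delay 16 s,
  unit dispersions, peak:undershoot ratio 6, 32 s support — the conventional
  canonical parameterisation. The sampled kernel is normalised to a maximum
  of 1, so amplitudes are in units of peak response.
* **Solver.** The normal equations are solved through a rank-revealing QR
  decomposition; a rank-deficient design is a hard error that names the
  collinear columns. No silent pseudo-inversion, no prewhitening, no
  temporal filtering — estimation is plain OLS and fully deterministic.
* **Motion screening** (`screen_motion()`): "total displacement" is defined
  here as the maximum over scans of the Euclidean norm of the three
  translations relative to the first scan, with a strict 3 mm exclusion
  threshold. Rotations are monitored but not included in the scalar; other
  summaries exist in the literature and this one is deliberately simple and
  documented.
* The package operates on region-level time series. A small utility
  (`extract_roi_timeseries()`) averages voxels within 6 mm spheres around
  atlas coordinates for users starting from volumetric arrays; mean
  extraction commutes with the linear GLM, so estimating on region means is
  equivalent to averaging voxelwise betas.

When trials are far enough apart that their haemodynamic responses do not
overlap and all onsets share the same phase relative to the scan grid, LSS
is algebraically exact: the unit tests verify recovery at machine precision
in that regime, and equality with a one-regressor-per-trial GLM. With
overlapping responses LSS is an approximation — that is its purpose — and
recovery is assessed by correlation with ground truth instead. In the
noise-robustness check the noise standard deviation is matched to the
standard deviation of the noiseless signal series (signal-to-noise ratio 1
in the data domain, where the noise is added).

## Connectivity features

For the selected condition's trials (at least 3 required; 24 switch trials
in the default design), Pearson correlations between all region pairs form
the subject's symmetric FC matrix. Correlation coefficients are used
directly as features; a Fisher z-transform flag exists (`fisher_z = TRUE`)
but is off by default. The upper triangle is flattened in row-major order
(1,2), (1,3), ..., giving n(n-1)/2 features — 24,531 for a 222-region
network — with an explicit feature-to-region-pair map so selected features
can be localised.

## Classification protocol

Within every LOOCV fold the F-score of each feature is computed on the
training subjects only:

F(i) = [ (mean_pos(i) − mean(i))² + (mean_neg(i) − mean(i))² ] /
       [ var_pos(i) + var_neg(i) ]

with sample variances (n−1 denominators). Features are ranked by descending
score (ties broken by ascending index), the top k are kept, standardised to
the training fold's mean and SD (margin classifiers are scale-sensitive on
raw correlations; `standardize = FALSE` disables this), and a linear
max-margin classifier (hinge loss, C = 1, via libsvm) predicts the held-out
subject. Patients are the positive class throughout. Degenerate F-scores are
deterministic: zero denominator with positive numerator scores +Inf (ranked
first), zero/zero scores 0.

`sweep_feature_counts()` evaluates k over a grid (default 20, 40, ...,
up to the feature count exclusive — ending at 24,520 for 24,531 features)
and selects the *smallest* k attaining the maximal LOOCV accuracy.
Accuracy, sensitivity and specificity follow the confusion-matrix formulas
with patients positive; the ROC is traced by thresholding each subject's
signed decision score, and AUC is the tie-aware Mann–Whitney probability
that a random patient outscores a random control.

The permutation test shuffles group labels and reruns the LOOCV procedure —
feature ranking inside each fold included, so the null preserves the
selection optimism — at the fixed selected feature count. The p-value is
the plain exceedance fraction, `sum(null > observed) / n_permutations`,
with no +1 correction: an observed accuracy below every null value yields
exactly p = 1, above every null exactly p = 0. Whether the null should
rerun the entire feature-count sweep rather than the selected count alone
is genuinely ambiguous; rerunning the sweep is available via
`sweep_per_permutation = TRUE` and is the conservative (and far more
expensive) option.

## Network efficiency

Each subject's FC matrix becomes a weighted, undirected graph: diagonal
zeroed and negative correlations set to zero, since the weighted efficiency
formulas require nonnegative weights (absolute-value handling is available
behind `negative_weights = "absolute"`). The graph is thresholded at target
sparsities — the proportion of the n(n-1)/2 possible edges retained,
default 5% to 50% in 5% steps — keeping exactly `round(sparsity * n(n-1)/2)`
strongest edges (rounding half away from zero, ties broken by ascending
node-pair index, surviving weights preserved).

Edge weights convert to travel costs as length = 1/weight, the standard
convention for weighted efficiency. Global efficiency is the mean inverse
shortest path length over all ordered pairs (unreachable pairs contribute
zero). Local efficiency of node i sums, over ordered pairs of its
neighbours, the cube root of w_ij * w_ih / d_jh(N_i), normalised by
k_i (k_i − 1), where d_jh(N_i) is computed in the subgraph *induced by the
neighbours of i* — paths may not leave the neighbour set, reading the
neighbourhood definition literally. Nodes with fewer than two neighbours
contribute zero. The per-node neighbourhood shortest paths are computed by
a compiled Floyd–Warshall kernel; both metrics are validated against
brute-force path-enumeration oracles on small random graphs to 1e-10.

Each metric's curve over the sparsity axis is summarised by the trapezoidal
AUC (units: metric × sparsity width), and the per-subject AUC values are
compared between groups with Student's pooled-variance two-sample t-test
(df = n1 + n2 − 2; 90 for two groups of 46). No correction is applied
across the two metrics. Global efficiency is provably non-decreasing in
sparsity; local efficiency need not be.

## The synthetic cohort

`simulation_config()` + `generate_group_beta_series()` emulate the cohort
structure of a two-group task-switching study:

* 46 subjects per group, 222 regions partitioned into 10 communities,
  96 trials (24 switch / 72 repeat by exact construction; the first trial
  has no predecessor and is counted as a repeat so the two conditions
  partition all trials).
* Trial-wise responses are zero-mean multivariate normal with target
  correlation 0.4 within communities and 0.1 between — the range typically
  reported for within- versus between-network task connectivity — with the
  patient group offset by −0.1 (within) and −0.05 (between) by default:
  a modest, diffuse connectivity deficit. If the implied block correlation
  matrix is not positive semi-definite (possible for extreme settings),
  negative eigenvalues are clipped to 1e-10 and the matrix renormalised to
  unit diagonal; a matrix still non-PSD after repair is an error.
* Behaviour: control response times Normal(800, 100) ms with patients
  shifted +120 ms; accuracies Beta-distributed with a lower patient mean.
  These are plausible magnitudes for the qualitative group effects
  (patients slower and less accurate), not estimates of any dataset.
* Trial onsets sit on a jittered grid (mean ITI 6 s, jitter ±ITI/4 by
  default; both configurable, and jitter can be disabled for exact-recovery
  tests). Task timing beyond the switch/repeat structure is generic.
* All randomness derives from one top-level seed through named per-stage
  substreams; identical configuration and seed give bit-identical output.

`generate_bold_timeseries()` additionally synthesises scan-resolution
series (HRF-convolved sticks scaled by the amplitudes, optional confound
leakage, white Gaussian noise) plus a matching confound table, so the LSS
stage can be exercised against ground truth.

What the generator deliberately does **not** emulate: spatial structure and
voxel-level signal, temporally autocorrelated or physiological scanner
noise, scanner drift, condition-dependent amplitude means, learning or
fatigue effects, and site or acquisition heterogeneity. Passing tests on
this generator therefore demonstrate that the estimators and protocols are
correct and well calibrated under their own assumptions — not that any
particular real dataset will yield a particular accuracy or effect size.

## Validation choices and problem sizes

The test suite validates, among other things:

* exact switch/repeat bookkeeping and seeded determinism of the design
  generator;
* LSS recovery at machine precision in the non-overlapping noiseless
  regime and by correlation at signal-to-noise ratio 1;
* Monte-Carlo recovery of the generator's block correlations (500 trials,
  tolerance 0.05);
* chance-level calibration of the classifier on pure-noise cohorts
  (20+20 subjects, 500 features, 50 seeds: mean LOOCV accuracy within
  50% ± 5%, and permutation p-values consistent with uniformity by a
  Kolmogorov–Smirnov check), plus a leakage guard demonstrating that
  ranking features on the full data — the classic error — inflates noise
  accuracy while the fold-internal protocol does not;
* end-to-end effect recovery on a 46+46-subject, 222-region cohort with a
  within-community correlation deficit of −0.3, classified at a fixed
  feature count of 500 (a mid-scale count chosen for tractability of the
  200-permutation null; the full 20-step sweep is exercised on smaller
  problems) and analysed for lower patient global/local efficiency AUC;
* oracle equivalence of both efficiency metrics against brute-force
  enumeration on 100 random graphs of up to 8 nodes.

## Known limitations

* Plain OLS estimation: no autocorrelation modelling, temporal filtering,
  or regularised single-trial variants (least-squares-all is out of scope).
* Binary two-group design with patients as the positive class; no
  class-imbalance handling beyond balanced input, no nonlinear kernels, no
  nested selection of the regularisation constant.
* Connectivity is full Pearson correlation only — no partial correlation,
  tangent-space or shrinkage estimators.
* Graph analysis covers weighted global/local efficiency only; other
  topological measures (small-worldness, modularity, participation) and
  cluster-based edge inference are out of scope.
* The pipeline does no voxelwise preprocessing; it expects region-level
  series (or trial-wise betas) that have already been motion-corrected and
  normalised upstream.
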