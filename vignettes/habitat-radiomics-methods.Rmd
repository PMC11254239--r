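---
title: "Subregion habitat radiomics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subregion habitat radiomics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microsatellite instability (MSI) in rectal cancer predicts immunotherapy
benefit and prognosis, but pathological MSI testing samples a small part of a
spatially heterogeneous tumor. Whole-tumor ("classical") radiomics averages
imaging features over that heterogeneity, diluting signal that is carried by
focal subregions. This package implements a subregion ("habitat") radiomics
pipeline: each tumor is partitioned into a small, patient-specific number of
radiomically coherent subregions; per-subregion risk scores are averaged into
a patient-level score; and the resulting models are compared against
whole-tumor radiomics and clinicoradiological baselines, including the
downstream survival stratification.

## Pipeline and models

The analysis is a fixed sequence. Preprocessing per sequence (T2WI, T1WI,
DWI, CE-T1WI): multiplicative bias-field correction, z-score
standardization, isotropic resampling to 1 mm, fixed-bin-count
discretization to 32 gray levels computed over the in-mask intensity range.
The step order is part of the method; `preprocess_config()` rejects any
other order.

Habitat clustering per patient: voxels inside the tumor mask, described by
their 4-sequence z-scored intensity vectors, are soft-clustered by fuzzy
c-means into 10 preliminary clusters (fuzzifier m = 2, membership tolerance
1e-5, at most 300 iterations, k-means++ initialization — none of these are
externally prescribed, so they are package defaults). Each preliminary
cluster is then summarized by 368 secondary radiomic features (18
first-order + 74 texture, per sequence, no shape block), the feature columns
are standardized and projected by PCA onto the smallest number of leading
components carrying at least 0.85 of the variance, and a full-covariance
variational Bayesian Gaussian mixture with at most 10 components and a
Dirichlet weight-concentration prior of 1/10 merges radiomically similar
clusters. Components with posterior weight below 0.01 or without any
hard-assigned cluster are discarded; the survivors define the final V
subregions (1 <= V <= 10). Every preliminary cluster maps to exactly one
subregion, so the final map is a coarsening of the FCM partition.

Feature extraction: 18 first-order + 14 mesh/moment shape + 74 texture
features per sequence — 106 x 4 = 424 per region — extracted for every
subregion and for the whole tumor. The standard five texture families total
75 features; GLCM SumAverage is excluded (on a symmetric matrix it is twice
the joint average, hence redundant) to give the 74-feature block. Shape is a
property of the region geometry; it is computed once and emitted under each
sequence's namespace so that a full extraction is always 424 values.

Selection: a reproducibility filter (ICC(2,1), two-way random effects,
absolute agreement, threshold 0.75, computed from simulated second-rater and
repeat segmentations), a univariate logistic screen (alpha = 0.05 for
radiomic features), iterative correlation pruning at |r| > 0.75 (of the
worst pair, the feature with the higher mean absolute correlation is
dropped; ties break by feature id), LASSO with the penalty chosen to
maximize mean cross-validated AUC (a 1-SE alternative is available; under a
null design only the 1-SE rule is reliably sparse), and bidirectional
stepwise AIC. Clinicoradiological variables pass a univariate screen at
p < 0.1, stepwise AIC, and a multivariable p < 0.05 gate; odds ratios are
reported against the low-location and N0 reference levels.

Models: five elastic-net logistic regressions (clinicoradiological;
subregion radiomics; classical radiomics; subregion + clinicoradiological;
combined) with balanced class weights, an exhaustive grid over the mixing
parameter l1_ratio in {0, .1, .3, .5, .7, .9, 1} and inverse regularization
C on 7 log steps over 1e-3..1e2, scored by mean validation AUC over
stratified 10-fold cross-validation (ties resolve toward the stronger
penalty). The subregion model is trained on subregion rows, each labelled
with its patient's MSI status; its cross-validation folds are grouped by
patient so one patient's subregions never straddle folds. Patient-level
subregion scores are the arithmetic mean of the patient's V subregion
probabilities; probabilities (not linear predictors) are averaged because
the downstream Youden-cutoff stratification operates on a probability-like
scale. Training uses the training cohort only; a leakage guard raises an
error if an external-test patient reaches any fitting stage.

Evaluation: AUC with DeLong confidence intervals, paired DeLong tests
between models, F1/accuracy/sensitivity/specificity at each model's
training-cohort Youden cutoff with stratified bootstrap percentile intervals
(2000 replicates by default), decision curves on the grid 0.01-0.60,
Hosmer-Lemeshow calibration (deciles of risk), and Kaplan-Meier curves with
the log-rank test; 3-year disease-free survival is the product-limit step
function at 36 months.

## The synthetic cohort

No public imaging accompanies the study design this package targets, so the
generator is a first-class, tested module that plants known structure.

Each phantom patient is an ellipsoidal tumor on a regular grid whose
interior is partitioned into spatially contiguous habitats by weighted
nearest-seed (Voronoi) growth from random seed voxels. Each habitat has, per
sequence, a mean intensity and a spatially correlated Gaussian texture field
(correlation length in mm, realized by Gaussian smoothing of white noise),
so habitats differ in first-order and in texture statistics. On top sit
additive white noise, an optional multiplicative smooth bias field, and a
per-patient global intensity offset per sequence (SD 10 intensity units)
emulating scanner and patient variation.

An MSI-positive patient has the parameters of one focal habitat displaced:
mean intensities shifted by 4 units and the texture field's correlation
length and amplitude multiplied by 2.5 and 2. The affected habitat receives
a Voronoi weight of 0.72, making it roughly half the volume share of the
others (about a fifth of the tumor). These defaults realize the study's
premise — a focal high-risk subregion whose signal survives per-subregion
analysis but is diluted in whole-tumor averages: the per-patient intensity
offset dominates the diluted first-order shift, while the habitat-level
texture displacement remains detectable within the affected subregion.

Clinicoradiological covariates are drawn with the documented association
structure: higher tumor location multiplies the MSI odds (odds ratios 1.35
middle, 3.0 high vs low), nodal involvement multiplies them by 0.4, and the
remaining covariates (age, sex, CEA, CA19-9, T stage) are null. MSI
prevalence defaults to 53/475, the published cohort composition mirrored by
`reference_cohort_counts()`. Disease-free survival is exponential with a
MSS:MSI hazard ratio of 4 and a MSS 3-year survival of 0.35, with
administrative censoring at 60 months plus an independent exponential
dropout (rate 1/80 per month). Cohorts split 80/20 into training and
external test.

What the generator does **not** emulate: scanner physics, anatomy,
registration error (volumes are born aligned; the pipeline asserts rather
than performs alignment), non-exponential hazards, and any correlation
between covariates and imaging beyond the shared MSI label. Passing tests
therefore demonstrate internal correctness and the qualitative mechanism,
not clinical performance.

## Replicated model comparison

`model_comparison_study()` is the package's Monte-Carlo harness for the
central claim (subregion beats classical radiomics out of sample). A pool of
phantom patients is simulated once through the imaging stages; each
replicate draws a stratified training cohort from the pool, reruns
selection and all five fits on those patients only, and evaluates every
model on all remaining pool patients. Evaluating on the large pool
remainder, rather than a handful of held-out patients, keeps the
per-replicate AUC comparison from being dominated by test-set sampling
noise; replicate variability then reflects cohort composition and training
stochasticity. For null studies (zeroed MSI displacement) the evaluation
patients come from a second, independently simulated pool (`eval_pool`):
when training draws and evaluation remainder share one finite pool, drawing
the chance-high minority patients into training leaves chance-low ones for
evaluation, which biases the null held-out AUC below one half. Problem sizes used by the tests and the acceptance script —
pools of 50-120 patients on 20x20x16 grids with 60-patient training draws, 30-50 replicates, reduced
elastic-net grids — were chosen so the full study runs on a single CPU in
minutes; they are stated here as the package's own study design.

## Numerical choices and degenerate inputs

* FCM: points coinciding with a centroid get membership one (the standard
  singularity rule); empty hard clusters are dropped and labels compacted;
  fewer distinct points than clusters reduces the cluster count with a
  warning. The objective is non-increasing by construction and tested.
* VB-GMM: the Wishart prior expects a component covariance of the data
  covariance divided by 8 (`prior_scale`), with nu0 = d + 2 degrees of
  freedom. The scale sets the granularity at which clusters merge; 8 was
  chosen on planted-habitat and reference mixtures as the smallest value
  that does not under-merge well-separated habitats, and is configurable.
  Initializations: one-row-per-component, k-means solutions for k = 2..6,
  and random Dirichlet draws; the best evidence lower bound wins.
  Identical rows short-circuit to V = 1.
* Preliminary clusters below 10 voxels are merged into the nearest cluster
  by intensity centroid — texture matrices are unstable below this.
* Shape: the iso-surface is marching tetrahedra on the mask smoothed with a
  0.8-voxel Gaussian at iso-level 0.45; the level compensates the surface
  displacement the smoothing introduces. On a digitized ball of radius
  10 mm this pairing reproduces the analytic volume within about 1% and
  sphericity above 0.98. Degenerate single-voxel regions return zero axes
  with a warning.
* Discretization range is computed inside the mask (feature extraction only
  sees the mask); a constant region maps to level 1 with a warning.
* Elastic-net cross-validation adapts the fold count to the minority class,
  skips folds that cannot carry both classes, and falls back to the most
  regularized grid point (with a warning) when no valid resampling split
  exists; blocks whose training data cannot support a fit at all fall back
  to an intercept-only model. These paths exist for tiny cohorts and are
  exercised in the tests.
* All randomness flows from one master seed through a documented
  seed-derivation scheme, so every analysis is bit-reproducible.

## Known limitations

The habitat merge operates on 10 secondary-feature rows per patient; with
so few rows the mixture's model selection is only reliable when habitats
are well separated in feature space, and the variational bound can prefer
merging genuinely distinct but close habitats. Separation in feature space
also interacts with discretization: when between-habitat intensity offsets
dwarf the within-habitat texture, each habitat collapses onto a few gray
levels, texture features degenerate, and the secondary-feature rows of one
habitat stretch into "band gradients" that are hard to group — so the
planted-recovery phantoms use moderate offsets with strong textures, and
recovery on any single random phantom remains stochastic (roughly three in
four succeed); the recovery tests therefore run on fixed phantom sets. The 74-texture composition
excludes GLCM SumAverage by the package's own argument; other single-feature
exclusions would be equally consistent with a 74-feature count. ICC subjects
are simulated via boundary perturbation of the mask, which models
segmentation variability but not re-acquisition. The acceptance quantities
for model AUCs are Monte-Carlo means over replicates of a synthetic design,
not estimates on any clinical data.
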