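---
title: "Classifying whole-brain anatomical connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying whole-brain anatomical connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Probabilistic tractography on diffusion MRI yields, for every subject, a
count of streamline samples connecting each pair of brain regions. After
parcellating the cerebrum into the 90 AAL regions (45 per hemisphere), those
counts become a weighted anatomical network, and the question this package
addresses is whether two groups of subjects — patients and controls — can be
told apart from their whole-brain connectivity patterns, and if so, *which*
connections carry the discrimination.

`connclass` implements the full analysis as a reusable, tested pipeline:

1. **Connectivity construction.** With `n` seed voxels in region *i* and
   `S` samples per voxel (5,000 by default), region *i* emits `S * n`
   streamlines; if `m` of them reach region *j*, the directed strength is
   `m / (S * n)`, a fraction in [0, 1]. Because seeding direction matters,
   the undirected strength of a pair is the average of its two directed
   estimates, and strengths below a floor (0.01 by default) are zeroed to
   suppress false-positive connections. The result is a symmetric 90 × 90
   matrix per subject, flattened to a 4,005-long feature vector in a fixed
   row-major upper-triangle order.
2. **Group description.** Per-group mean matrices, an edge-wise two-sample
   t-test significance matrix, and a comparison of per-subject mean nonzero
   strengths.
3. **Classification.** Nested leave-one-out cross-validation (LOOCV): in
   every fold the left-out subject is removed *before* anything is fitted;
   the remaining subjects provide (a) the 50 most discriminating edges by
   two-sample t-tests, (b) standardization statistics, (c) a locally linear
   embedding (LLE) into 15 dimensions using 23 neighbors, and (d) a
   Gaussian-RBF support vector machine (kernel width sigma = 3). The
   left-out subject is projected through the out-of-sample LLE extension
   and scored. Sensitivity, specificity and the generalization rate follow
   `SS = TP/(TP+FN)`, `SC = TN/(TN+FP)`, `GR = (TP+TN)/N`, and the ROC/AUC
   treats every subject's decision score as a threshold.
4. **Significance and interpretation.** The generalization rate is compared
   against a permutation null in which cohort labels are shuffled and the
   *entire* nested pipeline is rerun; consensus features — edges selected
   in every fold — are extracted with per-region incidence weights and a
   network/subnetwork annotation.

# Worked example

```{r, eval = FALSE}
library(connclass)

cfg <- simulation_config(seed = 1,
                         effect_multiplier = effect_multiplier_for_d(1.5))
cohort <- generate_cohort(cfg)      # 90 regions, 22 patients + 26 controls
cv <- run_loocv(cohort, pipeline_config())
cv
#> LOOCV over 48 subjects: GR = 95.8%, SS = 90.9%, SC = 100.0%, AUC = 0.9790
#>   confusion: TP=20 TN=26 FP=0 FN=2

consensus <- consensus_features(cv, cohort)
head(sort(region_weights(consensus), decreasing = TRUE))
```

# The synthetic cohort generator

No subject-level data accompany the study this analysis design comes from,
so the generator is a first-class module that emulates the *statistical
structure* the pipeline assumes, and every quantitative guarantee of the
package is stated against it.

**Mechanism.** A symmetric support of edges is drawn at density 0.30 of the
4,005 off-diagonal pairs (sparse, but far above the 33 affected edges; real
tractography networks at this parcellation are similarly sparse after
thresholding). Template strengths on the support are log-normal
(`meanlog = log(0.04)`, `sdlog = 0.4`), giving the right-skewed, positive
strength distribution characteristic of normalized tract counts. Each
subject multiplies every edge mean by two independent mean-one log-normal
factors: a per-edge noise (`subject_log_sd = 0.35`, a ~36% coefficient of
variation, typical of probabilistic-tracking reproducibility) and a global
per-subject scale (`subject_scale_sd = 0.10`). The global factor is what
gives per-subject mean strengths a realistic spread: group means of
0.0499 / 0.0412 with between-subject SDs near 0.005 imply a ~10%
coefficient of variation that independent per-edge noise alone cannot
produce. The strength floor is applied after noise, in the same position as
in the real pipeline.

**Calibration.** Control edges are scaled once so the expected mean nonzero
strength is `target_mean_control` (0.0412). The patient group is then
calibrated to `target_mean_patient` (0.0499) in one of two ways:

* `effect_multiplier = NULL` (default): the ratio on the affected edges is
  solved in closed form so the patient target is met with all other edges
  at control level — the entire group contrast is concentrated on the
  implanted edges.
* explicit `effect_multiplier`: the affected edges keep exactly that ratio
  and the *remaining* patient edges share a solved global background
  elevation. This mirrors the structure reported for real patient
  connectomes — an overall strength increase on top of concentrated
  effects — and is why, on such cohorts, every consensus edge's direction
  is expected to be "increased". When the multiplier alone already
  overshoots the patient target the background is held at 1 with a
  warning.
* `effect_multiplier = 1` denotes an exact per-edge null cohort; the
  patient target is deliberately ignored, since a null has no group
  contrast to calibrate.

`effect_multiplier_for_d()` converts a per-edge Cohen's *d* into the
multiplier under the generator's own noise model
(`cv = sqrt(exp(subject_log_sd^2 + subject_scale_sd^2) - 1)`, pooled-SD
convention), so cohorts with a prescribed standardized effect size can be
built without manual algebra.

**What the generator does not emulate.** Spatial autocorrelation between
edges sharing a region, distance-dependent connection probability, hub
structure, asymmetric directed-count noise, and registration artifacts are
all absent. Passing tests therefore demonstrate that the *pipeline* is
correct and calibrated — unbiased selection, leak-free cross-validation,
honest permutation p-values — not that comparable accuracy would be reached
on clinical data.

# Numerical and design choices

* **Strength normalization.** The directed strength is the reached fraction
  `m / (S * n)`; values are necessarily in [0, 1] and compatible with the
  0.01 floor and with observed mean strengths near 0.04–0.05. The floor is
  applied after symmetrizing, since it targets the (undirected)
  connectivity value itself.
* **Feature selection.** Classical pooled-variance (Student) two-sample
  t-tests, vectorized over edges for speed and verified against
  `stats::t.test` per column; Welch is available by configuration. Ranking
  ties are broken by larger |t| and then by smaller edge index; edges with
  zero variance in both groups get p = 1. A `p_ceiling` (default 0.001)
  only warns — selection always keeps exactly `n_features` edges.
* **LLE.** Neighbor search is Euclidean with ties broken by index. The
  local Gram system carries a ridge of `reg * trace(C)/k` with
  `reg = 1e-3`; the ridge is mandatory whenever `k` exceeds the feature
  dimension and at exactly reconstructable points, where the Gram matrix is
  singular. The embedding takes eigenvectors 2..d+1 (ascending eigenvalue)
  of `(I - W)'(I - W)` from a dense symmetric solver — cohorts here have at
  most a few dozen subjects, so sparse machinery would be overhead — and
  columns are scaled to unit variance, making downstream RBF kernels
  invariant to the eigenvector sign/rotation ambiguity. The out-of-sample
  extension reconstructs a new point from its k nearest training points
  with the same constrained weights and maps those weights through the
  training embedding: the original formulation fits the training set only,
  so a standard extension is the package's explicit choice for scoring the
  left-out subject.
* **Standardization.** Selected features are z-scored with training-fold
  statistics before LLE (distance-based methods should not be dominated by
  high-variance edges); toggleable.
* **SVM.** The kernel is the conventional Gaussian
  `exp(-||x - x'||^2 / (2 sigma^2))` with `sigma = 3`; a `sigma^2`
  denominator dialect is available. The soft-margin cost is not part of
  the published parameterization, so the package defaults to `C = 1` and
  records it in every run manifest. Decision scores are always oriented
  patient-positive.
* **Permutation test.** Whole-cohort labels are shuffled and the complete
  nested LOOCV — feature selection included — is rerun per permutation,
  the conservative reading of permutation testing for cross-validated
  accuracy. The p-value uses the add-one estimator
  `(#{null >= observed} + 1) / (B + 1)`, which cannot return 0.
* **Percentages** are carried at full precision and rounded to one decimal
  only in printed reports.

# Validation strategy and problem sizes

The test suite checks every numerical core against an independent oracle:
LLE weights against a constrained least-squares KKT solve and the embedding
against a dense eigendecomposition of the oracle's weight matrix; SVM
decision values against a hand-written SMO dual solver (and kernlab);
AUC against the Mann–Whitney pairwise count (and pROC); edge-wise t-tests
against `stats::t.test`; the sampled permutation p against exhaustive
enumeration on a 4-subject cohort.

Statistical guarantees are exercised at sizes chosen to keep the full suite
fast while preserving power: null-calibration runs use 20-subject,
24-region cohorts with 99 permutations (training sets of 19 cannot support
k = 23 neighbors, so those runs use `n_features = 20`, `k = 7`, `d = 4`),
while recovery runs use the full study geometry — 90 regions, 22 + 26
subjects, 33 implanted edges at per-edge d ≈ 1.5, default pipeline
parameters. With 50 features selected per fold and only 33 implanted edges,
17 slots per fold necessarily go to boundary edges; the fold intersection
prunes most but not all of them, so consensus precision against the
implanted truth sits near 0.8 by construction, with recall near 1 and
every consensus direction "increased".

# Limitations

* The pipeline fixes its hyperparameters (50, 23, 15, 3) rather than
  searching for them; reproducing a tuning protocol on real data is out of
  scope.
* LOOCV accuracy on null data is mildly anti-conservative (below 50% on
  average) — a known property of leave-one-out with small samples, since
  the left-out subject's class is always underrepresented in training. The
  permutation test inherits and absorbs this bias, which is precisely why
  it, and not the raw accuracy, carries the inference.
* Annotation of consensus connections (cortical-limbic networks and their
  subdivisions) is a packaged lookup, not an inference; pairs outside the
  lookup receive a coarse lobe-pair tag.
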