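---
title: "Perinodular radiomics for STAS: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perinodular radiomics for STAS: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peristas)
```

## The problem and the model

Spread through air spaces (STAS) is a histologic invasion pattern of
lung adenocarcinoma: micropapillary clusters, solid nests or single
tumor cells in the alveolar spaces beyond the edge of the main tumor.
It matters surgically (limited resection of a STAS-positive tumor
carries a higher recurrence risk) but is invisible to conventional CT
reading. The working hypothesis behind this package is that the lung
parenchyma *around* a nodule carries quantitative texture information
about STAS, so a radiomic model combining intranodular and perinodular
features should outperform a model restricted to the tumor body.

The analysis chain is:

1. **VOI construction.** Given a nodule (core) mask and a lung mask on
   a common grid, build eight volumes of interest: the core itself,
   cumulative perinodular shells reaching 2, 4, 6, 8, 10 and 20 mm from
   the tumor surface, and a tumor–lung interface band spanning 3 mm on
   either side of the contour. Every perinodular VOI is the dilated
   core intersected with the lung field minus the core, so shells are
   nested and never contain extrapulmonary tissue — essential for
   subpleural nodules, where naive spherical dilation would sample the
   chest wall.
2. **Feature extraction.** Each VOI yields 851 features: 14 3D shape
   descriptors plus 93 intensity/texture features (18 first-order and
   24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) on the original image
   and on each of the eight bands of a single-level 3D wavelet
   transform (14 + 9 × 93 = 851); eight VOIs give 6,808 features per
   case.
3. **Modeling.** Per model: z-score standardisation, removal of one
   member of every feature pair with |ρ| > 0.99, SMOTE class
   balancing, recursive feature elimination (RFE) under an AdaBoost
   classifier down to 20 features, and a final AdaBoost fit; model
   probabilities are estimated out-of-fold with stratified 5-fold
   cross-validation, all preprocessing refitted inside each training
   fold. Nine models are compared: one per VOI plus the combined
   eight-VOI model.
4. **Evaluation.** ROC/AUC with Youden-index operating points,
   percentile bootstrap confidence intervals and DeLong comparisons.

## Geometric construction

Morphological dilation and erosion are realized by thresholding an
exact Euclidean distance transform computed with the physical voxel
spacing (Felzenszwalb–Huttenlocher lower-envelope algorithm per axis).
A voxel belongs to the dilation by $d$ mm iff the distance from its
centre to the nearest mask-voxel centre is $\le d$; boundary voxels at
exactly $d$ are included. This gives millimetre-accurate morphology on
anisotropic grids, where iterated structuring elements would not. The
erosion is the dual (distance to the mask complement $> d$), so thin
structures vanish under erosion exactly when no voxel is deeper than
$d$.

Shells are *cumulative* (surface to $d$), matching a progressively
growing perinodular region; annular rings between two distances are
available via `annularRing()`. Multiple connected components of a core
mask are treated as one region. All eight VOIs of a case are pure
functions of (core, lung, spacing).

## Feature definitions and numerical choices

- **Discretization**: fixed bin width of 25 HU anchored at the VOI
  minimum (`level = floor((x - min)/25) + 1`). Min-anchoring makes all
  discretized texture features invariant to global intensity shifts.
  25 HU is common chest-CT practice; it is configurable
  (`discretizationConfig`). No resampling is applied — the intended
  inputs are ~1 mm near-isotropic reconstructions, and the geometry
  code handles residual anisotropy in physical units.
- **Texture matrices** use the 26-neighbourhood at Chebyshev distance 1
  (13 unique directions). GLCM is symmetric, features averaged over
  directions (not merged matrices); GLRLM likewise per-direction
  averaged; GLSZM zones are 26-connected; GLDM uses dependence
  $\alpha = 0$ with the centre voxel counted in the dependence size;
  NGTDM uses the mean absolute difference to the in-mask neighbour
  mean. Degenerate (single-level) regions follow $0\log 0 = 0$ limit
  conventions and never produce `NaN`.
- **First-order**: 18 statistics; entropy/uniformity on the discretized
  histogram, moments as population moments, kurtosis not
  excess-corrected, percentiles by linear interpolation.
- **Shape**: surface area and mesh volume from a marching-tetrahedra
  iso-surface at level 0.5 of a lightly smoothed (σ = 0.8 voxel) mask
  indicator. Meshing the raw binary indicator overestimates the area of
  a digital sphere by ~25–30% (staircase artifact); the anti-aliased
  surface brings it within a few percent, which is what makes the
  sphericity of a digital ball land near 1. Structures thin enough for
  smoothing to erase (maximum smoothed value < 0.7) fall back to the
  raw midpoint mesh so single-voxel and sliver masks stay defined.
  Axis lengths come from the eigenvalues of the voxel-coordinate
  covariance ($4\sqrt{\lambda}$); maximum diameters are exact largest
  pairwise distances between boundary-voxel centres (per slice/row/
  column for the 2D variants), computed after a convex-hull-candidate
  reduction.
- **Wavelets**: single-level periodized orthonormal Coiflet-1
  transform, applied as an explicit orthogonal matrix per axis, so
  Parseval's identity holds exactly. Each of the eight bands is
  reconstructed back to the original resolution with the other bands
  zeroed; the reconstructions sum to the input image and masks apply
  unchanged. Odd axes are padded by edge replication and cropped after
  reconstruction. The basis choice is a convention, not a claim — any
  orthogonal wavelet would do; only the band count and limit behaviour
  are contractual.
- **Extraction window**: features are computed on the mask bounding box
  grown by 8 voxels, a pure function of the mask, so per-VOI blocks of
  the case-level vector are bit-identical to single-VOI extraction.

## Modeling choices

- **Split**: stratified 80/20 with `floor` rounding per class; a 56/160
  cohort gives 44 + 128 = 172 training and 44 test cases. (A published
  variant of this design reports 46/126 training cases, which is not an
  exact stratified 80% of 56/160; exact rounding is implemented here.)
- **PCC filter**: threshold 0.99 on the *absolute* correlation, so
  anti-correlated duplicates are also removed; features are scanned in
  name order and the later member of an offending pair is dropped,
  making the reduction deterministic.
- **SMOTE**: synthetic minority cases interpolate between a minority
  case and one of its 5 nearest minority neighbours; applied to
  training folds only. Oversampling before splitting would leak
  synthetic copies of test cases into training and is deliberately not
  supported by the pipeline functions.
- **AdaBoost**: discrete SAMME boosting of depth-limited CART trees
  (rpart with case weights), 50 stumps by default; probability = the
  alpha-weighted vote fraction. The boosting loop draws no random
  numbers, so fits are deterministic for fixed data. Hyperparameter
  grid search covers {50, 100, 200} estimators × depth {1, 2, 3},
  scored by mean validation-fold AUC, ties resolved toward fewer
  estimators, then shallower trees.
- **RFE** ranks features by accumulated alpha-weighted split
  improvement and halves the feature set per iteration until the
  target count (20 by default) is reached; ties and unused features
  rank alphabetically for determinism. RFE is nested inside each grid
  evaluation and inside each CV training fold.
- **CV probabilities**: stratified 5-fold; each case's reported
  probability is the mean of its out-of-fold probabilities across
  iterations (default 5 in `modelSpec`; the cohort-scale test runs use
  1 iteration as their problem size).

## The phantom generator

The generator emulates the study conditions the analysis assumes rather
than anatomy: two ellipsoidal lung fields at −800 HU inside a
soft-tissue body, nodules with mean diameter 19.7 mm (SD 6.2, truncated
to [8, 32] mm — the upper cut reflects the usual ≤5 cm inclusion limit
while keeping the 20 mm perinodular margin inside a compact 96×84×84
grid), consolidation-to-tumor ratio 0.7 ± 0.3 realized as a solid
(+30 HU) sub-ellipsoid inside a ground-glass (−450 HU) nodule, optional
pleural contact (probability 0.25), and additive Gaussian noise of
30 HU. Nodule axes receive mild volume-preserving anisotropy so shapes
are not perfect spheres.

STAS-positive cases additionally receive a *strictly perinodular*
planted signal scaled by `peritumoralEffect` (default 1): Gaussian
blurring of the outer 3 mm interface zone, Poisson-scattered hyperdense
0.5–1.5 mm-radius satellites within the 10 mm shell (λ = 6·effect), and
excess intensity noise (SD 15·effect HU) in the same shell. Nothing
inside the core is modified, so an intranodular model is handicapped by
construction — the design property the cohort-scale tests verify. At
`peritumoralEffect = 0` the positive branch is skipped entirely and a
positive case is voxel-identical to a negative case with the same seed,
which gives the null-calibration tests an exact control.

What the phantoms do **not** emulate: airway/vessel trees, lobar
anatomy, scanner/dose/reconstruction-kernel effects, histologic
subtypes, and any intranodular class difference (real STAS+ tumors
have, e.g., higher CTR). Passing tests on phantoms therefore
demonstrates that the *pipeline* recovers a perinodular signal when one
exists and invents none when it does not — they say nothing about the
effect size in real patients.

All randomness flows through one master seed; per-case seeds are
derived as a deterministic integer hash of (master, index), and every
stochastic function takes an explicit seed and restores the caller's
RNG state.

## Problem sizes used by the tests

The cohort-scale properties run on 216-case cohorts (56 positive / 160
negative) over ten master seeds with first-order features per VOI and
one CV iteration — chosen as the smallest configuration that exercises
the full imbalance-aware chain at the intended cohort size. The
zero-signal cohorts reuse the (bit-identical) negative cases of the
planted cohorts and regenerate only the positives, an equivalence the
test suite itself verifies. The null-calibration acceptance check
evaluates each model's median out-of-fold AUC across the ten seeds;
medians are used because a single null AUC on 216 cases has a standard
deviation of several points, and the claim under test is about the
models, not about any single draw. Pipeline determinism is demonstrated
on a 16-case run; determinism is a structural property (explicit
seeding everywhere), not a statistical one, so the small size loses
nothing.

## Known limitations

- Feature *values* are implementation-defined where the field has no
  single convention (bin width, wavelet basis, direction aggregation);
  counts, invariants, limit behaviour and oracle agreement are the
  tested contracts.
- The mesh-based surface area is an anti-aliased estimate; it is
  accurate for blob-like VOIs (within a few percent on digital balls)
  but rounds sharp corners — a small cube's area and volume read
  10–20% below the voxel-box values. Clinical nodules and shells are
  blob-like, so the ball regime is the relevant one.
- SMOTE distances are unweighted Euclidean in the standardized feature
  space; with very small minorities the neighbour count shrinks with a
  warning.
- The binary-sign AUC convention (sens + spec)/2 applies to single
  binary predictors only; continuous scores go through the full ROC
  machinery.
- `pccFilter` materialises the feature correlation matrix; at 6,808
  features that is ~370 MB transiently. Within cross-validation the
  filter runs after scope/group selection, which keeps typical blocks
  far smaller.
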