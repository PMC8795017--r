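---
title: "Methods: radiomics and machine learning for labyrinth MRI classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics and machine learning for labyrinth MRI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`labradiomics` implements a complete radiomics pipeline for computer-aided
diagnosis of Menière's disease (MD) from conventional T2-weighted MRI of the
inner-ear labyrinth: preprocessing of image/mask pairs, extraction of 812
quantitative features, PCA-based reduction to 10 components, a multi-layer
perceptron (MLP) classifier, and diagnostic evaluation under a center-aware
train/test split and 10-fold cross-validation. Because no clinical MRI data
are distributable with the package, a first-class synthetic cohort generator
produces seeded multi-center labyrinth phantoms with the statistical
structure the analysis assumes, so that every downstream stage is testable
end to end.

The classification model is deliberately simple: per-ear feature vector
$x \in \mathbb{R}^{812}$, standardized per feature on training rows, projected
onto the top $k = 10$ principal components, then classified by an MLP with
one 500-unit ReLU hidden layer and a 2-unit softmax output trained with Adam
(learning rate $10^{-3}$) under early stopping. The patient class is coded 1.

## The synthetic phantom and what it does (not) emulate

Each ear is a *labyrinth-like phantom*: a vestibule modelled as an ellipsoid
(default semi-axes 4.0 x 3.2 x 2.8 mm) plus three mutually orthogonal
half-torus arcs (major radius 5.6 mm, tube radius 0.9 mm, plane offsets
2 mm) standing in for the semicircular canals. The arcs are restricted to
disjoint half-spaces, so the union volume has the closed form
$\tfrac43\pi abc + 3\pi^2 R r^2$ — this is what the voxelized mask volume is
tested against. Per-subject anatomy varies by a 2% lognormal scale jitter.

Intensities follow a two-tissue model: bright fluid-filled ROI (mean 100)
over dark surroundings (mean 30), in arbitrary units. Within-ROI texture is
white noise smoothed to a 1.0 mm correlation length and scaled to SD 1.5;
independent acquisition noise (SD 2, Gaussian by default, Rician magnitude
optionally) is added everywhere. Scanner differences between the four
centers A–D are an affine intensity transform (scale/offset) plus a
center-specific anisotropic acquisition spacing.

The *patient effect* is a focal hypointense sub-region of the vestibule — a
saccule-like structure — in which intensities drop by a fixed delta. The
default "strong" effect is a drop of 6 units (three times the acquisition
noise SD) over 15% of the ROI volume; optional effects shift the texture
correlation length or dilate the ROI. Setting every effect field to 0
yields identically distributed classes (the null cohort). The delta is
expressed in raw intensity units, the same units as the noise SD, so effect
size statements like "3x the noise SD" are literal.

Design notes on the center effects: Z-score normalization removes affine
intensity differences *exactly*, so intensity scale/offset can differ freely
between centers. Spacing differences, however, act through interpolation:
resampling a coarser acquisition smooths texture and shifts texture
statistics in ways no per-image normalization can undo. The default spacings
place the external test center D *within* the range spanned by the training
centers (A 0.5/0.5/0.6, B 0.45/0.45/0.65, C 0.55/0.55/0.5, D 0.5/0.5/0.55 mm);
with D far outside that range the interpolation-induced shift is not
identifiable from training data by any method, which would test the cohort
design rather than the pipeline. The phantoms do not emulate anatomically
accurate cochlear geometry, partial-volume physics, bias fields, motion, or
k-space effects; passing tests therefore demonstrate pipeline correctness
and recoverability of a planted effect, not clinical performance on MD.

## Preprocessing

1. **Isotropic resampling** to 0.5 mm voxels by separable tensor-product
   cubic splines. Spline interpolation is linear in the samples, so each
   axis is resampled through a precomputed interpolation matrix (built from
   `stats::spline` impulse responses, `method = "fmm"`); the mask is
   interpolated as a float field and re-binarized at 0.5. The output grid
   keeps the input origin and preserves world extent to within one voxel.
2. **Z-score normalization**: mean 0, population SD 1 over the full volume
   (the `scope = "roi"` switch restricts the statistics to the mask).
   The two-voxel image {10, 20} maps to {-1, +1} (population convention).
3. **Fixed-bin-width discretization** with width 0.5 in normalized units:
   level $\lfloor (x - \min_{ROI})/0.5 \rfloor + 1$, bin edges anchored at
   the ROI minimum (the anchor is a convention; it makes discretization
   invariant to intensity shifts).

## The 812-feature roster

20 shape features plus 88 intensity/texture features on each of 9 image
versions (original + 8 stationary wavelet sub-bands): $20 + 9 \times 88 = 812$.
The 88 split into 18 first-order statistics, 26 GLCM, 16 GLRLM, 16 GLSZM,
7 GLDM and 5 NGTDM features, following the published formula families for
these matrices. Original-image features are unprefixed (`Stats_min`,
`GLCM_contrast`, ...); sub-band features carry a `wavelet_LLL_` ... prefix.

Conventions that the formulas do not themselves fix, chosen once and tested:

* **Wavelet filter**: single-level *stationary* (undecimated) 3D transform
  with the Coiflet-1 kernel and periodic boundary handling; every sub-band
  lives on the input grid so the original mask applies unchanged. Each
  sub-band is independently re-discretized with bin width 0.5 over the ROI.
* **GLCM**: symmetric matrices at Chebyshev distance 1; the 26 scalar
  features are averaged over the 13 unique 3D directions (directions with
  no valid pair are skipped). Degenerate single-level ROIs take limit
  values (entropy 0, energy 1, correlation 1).
* **GLRLM**: run-length matrices per direction, features averaged over the
  13 directions. **GLSZM**: zones are 26-connected equal-level components.
  **GLDM**: dependence size = the voxel itself plus equal-level
  26-neighbors ($\alpha = 0$). **NGTDM**: 26-neighborhood mean gray level;
  constant ROIs give coarseness capped at $10^6$ and busyness/strength 0.
* **Percentiles**: linear interpolation between order statistics
  (`quantile` type 7). Population variance throughout. Skewness/kurtosis
  of a constant ROI are defined as 0.
* **Shape**: surface quantities come from a triangulated isosurface of the
  lightly Gaussian-smoothed (sigma 0.9 voxel) binary mask, extracted by
  marching tetrahedra at level 0.5. Smoothing acts as anti-aliasing: the
  digital-ball surface area then converges to the analytic value
  (sphericity 0.99 for a radius-10-voxel ball) instead of the ~1.5x
  staircase overestimate of a raw voxel surface. Mesh volume uses the
  divergence theorem on the oriented triangles. Maximum 3D/2D diameters are
  exact maxima over boundary-voxel centres. Axis lengths are
  $4\sqrt{\lambda_i}$ from the inertia eigenvalues of the voxel centres.
  One known numerical property: because the six-tetrahedron cube
  decomposition singles out a cube diagonal, mesh-derived features are
  invariant under 90-degree grid rotations only to about 0.2% (all other
  shape features are exactly invariant); this is far below the scale of
  biological shape variation the features are meant to measure.

Before filtering, the image/mask pair is cropped to the ROI bounding box
plus a 4-voxel margin. The margin covers the 6-tap filter support, so every
ROI voxel's sub-band value is identical to the uncropped computation while
the cost of texture extraction is bounded by the ROI, not the field of view.

## Reduction and feature contributions

Features are standardized with training-row means/SDs (near-constant
features, SD < 1e-12, are clamped to SD 1, which zeroes them after
centering); PCA retains 10 components with a deterministic sign convention
(largest-|loading| entry positive). Test rows always use the training
standardizer — the protocol is leakage-free.

Per-feature importance is the *mean absolute loading* across the 10
components, normalized by its maximum so scores live in [0, 1]; features
above 0.7 form the selected set. This is a documented operationalization of
"inverse-PCA mean contribution with a 0.7 cutoff": from orthonormal
loadings alone an absolute 0.7 threshold is not meaningful, so the
normalized scale anchors the cutoff to the most influential feature.

## Classifier and early stopping

The MLP (10 -> 500 ReLU -> 2 softmax) minimizes mean cross-entropy with
seeded mini-batch Adam (batch 32, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
learning rate $10^{-3}$), at most 1000 epochs. A stratified 10% internal
validation split is carved from the training data — never from the test
set, avoiding the leakage that using an external set for early stopping
would introduce. Training halts when validation loss has not improved for
20 epochs and the best-epoch weights are restored. Two details matter on
small cohorts and were chosen deliberately:

* *Mini-batches rather than one full-batch step per epoch*: with a single
  update per epoch, a 20-epoch patience window spans only 20 Adam updates,
  and training stops long before the loss landscape has been descended.
* *A 100-epoch warm-up before early stopping arms* (and before best-epoch
  tracking starts): with ~10-20 validation samples the validation loss is
  noisy, and an early spurious minimum would otherwise freeze an underfit
  model.

Everything (initialization, batch shuffling, the validation split) is
driven by one seed; identical configuration and seed give bit-identical
weights.

## Evaluation

The center-aware split sends all of center D to the test set and tops it up
with a seeded random draw from the other centers until the test set holds
26% of the cohort (rounded); on the study-shaped 260-ear cohort this gives
exactly 192 train / 68 test. Cross-validation is stratified by class
(10 folds of 26 on the full cohort). Metrics: accuracy, sensitivity,
specificity, PPV, NPV as percentages, F1, Matthews correlation coefficient,
and a rank-based (Mann–Whitney, midrank-tied) AUC. Confidence intervals are
95% percentile bootstrap over 2000 class-stratified resamples; degenerate
resamples are skipped and counted. A utility reconstructs the integer
confusion matrix consistent with published sensitivity/specificity
percentages at known class sizes, which pins the printed metric table to
exact integer arithmetic in the tests.

## Problem sizes and numerical checks

The test-suite and acceptance-script experiments use the study-shaped
cohort (120 patients / 140 controls across centers A–D, 24 ears at D) on
48^3 acquisition grids — small enough that a full end-to-end run completes
in minutes on one CPU while leaving every stage nontrivial (ROIs of ~2300
voxels at 0.5 mm after resampling). Texture-matrix construction is verified
against brute-force pair/run/zone enumeration on random small grids; the
wavelet against direct 3D convolution; shape against analytic spheres; the
AUC against an independent ROC implementation; and the published-table
worked examples against exact integer confusion matrices. The null-cohort
acceptance check asserts chance-level accuracy within the 95% binomial
band, which by construction fails for ~5% of seeds under a correct
implementation; the packaged tests pin a seed for reproducibility.

## Known limitations

* Phantom realism is limited (see above); in particular partial-volume
  boundary voxels dominate the low-intensity histogram tail, which is why
  recovery of the focal effect rests on mid-histogram and texture features
  rather than on `Stats_min`/`Stats_p10` as one might expect clinically.
* The exact composition of the original 812-feature roster is proprietary
  to its vendor; this package fixes a documented roster with the same
  total and family structure.
* Mesh-derived shape features carry the ~0.2% rotation equivariance noted
  above.
* The feature-contribution score is a documented reconstruction, not a
  vendor-verbatim formula; the selected-feature *mechanism* is
  reproducible, a specific clinical 15-feature list is not.
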