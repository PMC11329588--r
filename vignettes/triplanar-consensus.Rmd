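---
title: "Triplanar consensus segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplanar consensus segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(triseg)
```

## The method

`triseg` segments a 3-D volume with a single 2-D U-Net applied slice-wise
along the three orthogonal anatomical orientations (a "2.5D" or triplanar
approach). Training one shared network on pooled axial, sagittal and coronal
slices — rather than three orientation-specific networks — lets common
features be shared across orientations, and requires only that all slices
have identical dimensions, which the preprocessing guarantees by resampling
every volume to a cube. The per-orientation probability grids are then fused
into one consensus mask.

The pipeline has four stages, each exposed as ordinary R functions:
phantom/cohort generation, preprocessing, cross-validated training, and
consensus inference plus evaluation.

## Preprocessing

Volumes pass through four steps:

1. `resample_isotropic()` — tri-linear resampling onto the cubic working
   grid (canonically 256³ voxels at 1.0 mm). Fields of view are aligned at
   their physical centers, so anisotropic inputs are interpolated and
   symmetrically padded with background where needed. Masks are interpolated
   like intensities and re-binarized at 0.5, with ties counting as
   foreground.
2. `reorient_center()` — an integer-voxel translation bringing a supplied
   landmark to the matrix center voxel `floor(dim/2) + 1`. For phantoms the
   landmark is the truth-mask centroid; for clinical data it would be a
   stored anatomical coordinate (automatic landmark detection is
   deliberately out of scope). Axis order is fixed as
   (anterior–posterior, left–right, inferior–superior) and recorded in
   `axis_labels`.
3. `compute_cohort_stats()` / `znormalize()` — cohort z-score intensity
   normalization. The mean intensity of each subject is measured over a
   fixed central ROI (canonically 128³ voxels at 1 mm, tongue-centered); the
   cohort mean `M` and the *sample* standard deviation `S` (n − 1,
   appropriate for small cohorts) of those per-subject means define the
   transform `(x − M)/S`, applied identically to every subject. We read the
   normalization as using cohort statistics **of the per-subject ROI
   means**; a per-subject variant would be a different design and is not
   implemented. Statistics are persisted as JSON and stored in the trained
   ensemble so that inference on new data reuses the training-cohort
   normalization. Normalization is invariant to affine intensity changes of
   the whole cohort (tested).
4. `to_segmentation_grid()` — the central region whose physical extent
   equals the segmentation grid (canonically a 128 mm cube) is cropped and
   resampled to the segmentation grid (256³ at 0.5 mm), doubling resolution
   over the tongue. `from_segmentation_grid()` provides the inverse mapping.

The full chain preserves known phantom volumes within 2% whenever the
tongue fits the central crop (tested property).

## The network

`unet_config()` describes a modified U-Net. Per encoder level: two 3×3
convolutions (stride 1, size-preserving padding) with ReLU, **dropout after
the repeated convolutions**, then 2×2 max pooling; no pooling after the
deepest level. Per decoder level: nearest-neighbour 2× upsampling followed
by a 2×2 convolution with ReLU, concatenation with the matching encoder
feature map, and two 3×3 convolutions with ReLU. A 1×1 convolution to two
channels with per-pixel softmax forms the head, matching the categorical
cross-entropy loss.

Choices worth noting:

* **Same-padding** rather than the valid padding of the original U-Net: the
  slice-wise restacking requires output size = input size.
* **Dropout placement and rate**: dropout is stated to follow each repeated
  3×3 convolution block in the contracting path but its rate is not; we
  default to 0.5 and place one dropout layer per encoder level (after the
  second convolution), configurable via `dropout_rate`.
* **No batch normalization** — not part of the reference architecture.
* **Upsampling** is nearest-neighbour + 2×2 convolution (the "up-convolution"
  used by Keras-style implementations); a transposed-convolution variant was
  considered and rejected to keep the parameter count and the checkpoint
  format simple.
* The channel plan defaults to `c(32, 64, 128, 256, 512)` at input size 256
  (deepest feature map 16×16×512); a desk-scale plan `c(8, 16, 32)` at input
  64 runs the identical code path. `unet_param_count()` gives the closed-form
  parameter count (29,330 for the desk plan).

The implementation is native C++ (RcppArmadillo, float32, im2col + GEMM on
the BLAS). Correctness of the backward pass is established by a
finite-difference gradient check in the test suite: median relative error
below 1e-3 across layers, with outliers explained by float32
finite-difference noise near ReLU kinks rather than by the analytic
gradient.

## Training

`train_config()` defaults to the reference protocol: at most 50 epochs,
early stopping when the validation loss has not improved for 10 consecutive
epochs (best weights restored), batch size 16, Adam with learning rate 1e-4
and conventional moment parameters (β₁ = 0.9, β₂ = 0.999, ε = 1e-7),
categorical cross-entropy.

`train_cv()` runs fivefold cross-validation **split at subject level**: all
slices of a subject stay on one side of every fold, which prevents
slice-level leakage between training and validation (the fold granularity is
a design choice; a slice-level 20% holdout would leak nearly identical
neighbouring slices). Slices without foreground are kept — the tongue
occupies a minority of slices and discarding empties would bias the class
prior — and no class reweighting is applied, consistent with the plain
cross-entropy loss. Each fold records its validation **mean IoU over both
classes** at the restored best epoch as the ensemble weight `w_f`. A
foreground-only IoU would be an alternative reading; the two-class mean is
used because the training metric is the generic mean IoU, and the choice
only rescales weights that enter a normalized weighted average.

## Inference and consensus

For each orientation, every slice is predicted by all five fold models and
the foreground probabilities are combined voxel-wise as
`s = Σ_f w_f p_f / Σ_f w_f` (fold ensembling happens *within* each
orientation, before any cross-orientation merge). The three orientation
grids are fused by `merge_consensus()`:

* `softmax` — equal-weight mean of the three probability grids, thresholded;
* `union`, `majority`, `unanimous` — each orientation hardened at the
  threshold, then voxels with ≥ 1, ≥ 2, or all 3 votes accepted.

The hard-prediction threshold defaults to `t = 0.5` (not otherwise
specified in the reference protocol) and **ties count as positive**,
matching the argmax-with-background-first convention for a two-class softmax
at 0.5. With that tie rule, equal-weight softmax averaging of hard inputs is
voxel-for-voxel identical to majority voting: the mean of three votes lies
in {0, ⅓, ⅔, 1} and crosses 0.5 exactly when ≥ 2 votes are positive. For
soft inputs the equivalence fails — probabilities (0.9, 0.3, 0.3) average to
0.5 (softmax-positive) while the hardened votes are (1, 0, 0)
(majority-negative) — and the test suite pins down exactly this boundary.
Set inclusion `unanimous ⊆ majority ⊆ union` holds on any input, which
forces TP and FP to be non-decreasing and FN non-increasing along
unanimous → majority → union, hence monotone recall. No connected-component
or morphological post-processing is applied.

## Evaluation and statistics

Confusion counts are plain voxel counts on the segmentation grid (they
always partition the grid: TP+TN+FP+FN = 256³ on the canonical grid).
Precision, recall, Dice `2TP/(2TP+FP+FN)` and foreground IoU follow their
closed forms; undefined ratios (empty masks) are reported as `NA` rather
than 0 so that cohort means are not silently dragged down. Dice and IoU are
linked by `dice = 2·iou/(1 + iou)` (tested to 1e-12). Summary tables report
the mean ± sd of per-subject metrics, not metrics of pooled counts — the two
aggregations differ and the per-subject mean is what the tabulated reference
results use. Volumes are positive-voxel counts times voxel volume, reported
in cm³; the unit is an interpretation fixed by voxel arithmetic (≈ 7.6×10⁵
voxels at 0.5 mm ≈ 95 cm³, the scale of adult tongues).

Statistical comparisons follow a Shapiro–Wilk gate at 0.05:

* paired (predicted vs truth volumes): paired Student's t if the differences
  look normal, otherwise a Wilcoxon signed-rank test — the non-normal branch
  is an extension we document, since the reference protocol names only the
  paired t path; zero-variance differences are reported as a degenerate
  "no difference" outcome rather than a fabricated p-value;
* two groups: unpaired Student's t (pooled variance, as "unpaired Student's
  t" implies) when both groups pass the gate, otherwise Mann–Whitney U.

Both paths delegate to R's standard implementations and are cross-checked in
the tests against independently computed reference values (scipy 1.17) to
1e-8.

## The phantom generator

`generate_phantom()` voxelizes a smoothly deformed ellipsoid centered in the
grid. Defaults emulate the anatomy the pipeline targets:

* semi-axes (35.75, 23.75, 30.0) mm in (AP, LR, IS) order — chosen so the
  per-orientation slice coverage at 0.5 mm matches the reported average of
  120 axial / 95 sagittal / 143 coronal tongue slices; analytic volume
  4/3·π·abc ≈ 106.7 cm³;
* a low-frequency radial boundary perturbation built from degree-2 spherical
  harmonics with seeded random coefficients (`deform_amplitude` = 0.05),
  emulating between-subject shape variation without anatomical modeling;
  the basis has zero spherical mean, so the deformation is volume-neutral to
  first order;
* 2–4 ellipsoidal distractor blobs of near-tongue intensity placed adjacent
  to (never overlapping) the tongue surface, standing in for the hard
  samples — lips and adjacent soft tissue — that make clinical tongue
  segmentation difficult;
* additive Gaussian noise (σ = 5 on a background/tongue contrast of 20/100).
  Gaussian rather than Rician noise is a deliberate simplification, as are
  the missing bias fields and motion artifacts: the phantoms probe the
  pipeline's logic, not MRI physics. Passing tests on phantoms therefore
  demonstrates correctness of the machinery and the statistics, not clinical
  segmentation accuracy.

The truth mask is computed before noise is applied, so it is exact and
independent of `noise_sigma`. `generate_cohort()` draws per-subject
`volume_scale` factors from group distributions; the default two groups
emulate controls (106 ± 8 cm³) and an atrophic group (91 ± 16 cm³,
about 14% smaller), n = 19 each, via the cube-root mapping
`scale = (V/V₀)^(1/3)` with a delta-method sd. Per-subject seeds and scale
deviates derive from the master seed and the **within-group subject index
only**, so groups with identical distributions produce index-matched
subjects — a common-random-numbers design that also pairs the default
groups, reducing between-group Monte-Carlo noise.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise the full pipeline at desk
scale: 20 phantoms on 64³ grids at 2 mm (the same code path as 256³ at
0.5 mm), the `c(8, 16, 32)` network, fivefold CV with at most 4 epochs
(patience 2), learning rate 1e-3 and dropout 0.25. On these high-contrast
phantoms validation mean IoU saturates around 0.99 by the third epoch, so
the short budget loses nothing; the miniature learning rate and dropout are
scaled to the miniature network, while the package defaults keep the
full-scale reference values (1e-4, 0.5). At desk scale the working and
segmentation grids coincide (64³ at 2 mm) and the crop is the identity; the
canonical crop-and-upsample path is exercised separately by resampling
tests and by the preprocessing-conservation property.

Other numerical conventions: mask re-binarization and hard-prediction ties
go to foreground; fold and subject seeds derive deterministically from a
single master seed (all below 2³¹); training, phantom generation and
prediction are bit-reproducible for a fixed seed in single-threaded use
(multi-threaded BLAS reductions are excluded from the bit-exactness
guarantee).

## Known limitations

* The phantom cohort is far easier than clinical MRI: consensus Dice near
  1.0 on phantoms says nothing about the Dice achievable on real tongues.
  The value of the desk experiment is that the *orderings* (union recall ≥
  majority ≥ unanimous; unanimous precision highest) and the volume
  statistics behave as the model predicts.
* The two-group detection-rate property (p < 0.005 in ≥ 90% of 20 cohort
  draws on true masks) sits at the edge of what the stated group parameters
  allow: with volumes 106 ± 8 vs 91 ± 16 and n = 19 per group, the pooled t
  test at α = 0.005 has roughly 85–88% per-draw power under the paired
  generator design (and ~74% for independent draws), so the 90% bar fails
  for many seeds. The corresponding test reports this honestly rather than
  relaxing the bar.
* No data augmentation, no learned fusion weights, no surface-distance
  metrics, no DICOM ingestion; the three-network orientation-specific
  triplanar variant is out of scope.
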