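# triseg

Triplanar consensus U-Net segmentation for volumetric MRI, with an
application to tongue-volume quantification.

## The problem

Measuring tongue atrophy in motor neuron disease requires segmenting the
tongue in routinely acquired T1-weighted head MRI — a low-contrast soft-tissue
structure whose manual delineation is slow and subjective. `triseg`
implements a 2.5D segmentation pipeline built around a **single 2-D U-Net
shared across the three orthogonal slice orientations**: the isotropically
resampled volume is segmented slice-by-slice in axial, sagittal and coronal
planes by one network, and the three per-voxel predictions are fused by a
consensus rule.

The pipeline, end to end:

1. **Preprocessing** — resample to an isotropic working grid, recenter on a
   tongue landmark, cohort z-score intensity normalization
   (`x ↦ (x − M)/S`, where `M` and `S` are the mean and sample SD of the
   per-subject mean intensities over a fixed tongue-centered 128³ ROI), then
   crop-and-upsample the central half of the field of view to the
   segmentation grid.
2. **Training** — pooled axial+sagittal+coronal slices of all training
   subjects train one U-Net (channels 32–512 at full scale) with categorical
   cross-entropy, Adam, batch 16, early stopping; fivefold cross-validation
   at subject level yields models `m_0 … m_4` with fixed weights
   `w_f` = each fold's validation mean IoU.
3. **Inference** — per orientation, every slice is predicted by all five
   folds and fold-ensembled as `s = Σ_f w_f p_f / Σ_f w_f`; the three
   orientation probability grids are fused by one of four strategies:

   | strategy  | rule |
   |-----------|------|
   | softmax   | threshold the equal-weight mean of the three probability grids |
   | union     | positive in ≥ 1 hardened orientation |
   | majority  | positive in ≥ 2 |
   | unanimous | positive in all 3 |

   On hard inputs, equal-weight softmax averaging is provably identical to
   majority voting; the package documents (and tests) where that equivalence
   stops for soft inputs.
4. **Evaluation** — voxel confusion counts, precision, recall, Dice
   (`2TP/(2TP+FP+FN)`), foreground IoU, tongue volume in cm³, Fig.-style
   overlays, and Shapiro–Wilk-gated paired / two-group volume statistics
   (paired t or Wilcoxon; unpaired Student t or Mann–Whitney U).

Because no public dataset of labeled tongue MRI exists, the package ships a
**synthetic phantom generator**: bright, smoothly deformed ellipsoidal
"tongues" (~90–110 cm³) with exact voxel ground truth, adjacent
near-tongue-intensity distractor blobs, Gaussian noise, and per-group
volume-scale distributions emulating a controls-vs-atrophy study
(106 ± 8 vs 91 ± 16 cm³, n = 19 per group). Every stage of the pipeline is
testable against these exact truths.

The U-Net itself (forward pass, backpropagation, Adam, dropout, early
stopping) is implemented natively in C++ (RcppArmadillo, float32,
im2col+GEMM) and verified against finite-difference gradients.

## Worked example

A desk-scale version of the full study (20 phantoms at 64³, fivefold CV,
miniature U-Net with channels 8–32):

```r
library(triseg)

cfg <- run_config(seed = 1, verbose = TRUE)
res <- desk_experiment(cfg)
res$table1[, c("strategy", "dice_mean", "precision_mean", "recall_mean")]
#>    strategy dice_mean precision_mean recall_mean
#> 1     axial 0.9993685      0.9993204   0.9994169
#> 2  sagittal 0.9990247      0.9983156   0.9997363
#> 3   coronal 0.9991736      0.9990736   0.9992744
#> 4   softmax 0.9999939      0.9999877   1.0000000
#> 5     union 0.9984307      0.9968690   1.0000000
#> 6  majority 0.9999244      0.9998488   1.0000000
#> 7 unanimous 0.9992131      1.0000000   0.9984276
```

On these high-contrast phantoms the consensus strategies saturate, but the
characteristic ordering of the fusion rules is visible: union maximizes
recall (1.0) at the lowest precision, unanimous maximizes precision at the
lowest recall, and softmax/majority balance both — the same qualitative
pattern reported for clinical tongue MRI. Held-out predicted volumes matched
the exact phantom truth volumes (92.2–108.7 cm³) to well under 0.1% mean
error.

The two-group atrophy study on a fresh 19 + 19 cohort:

```r
grp <- group_study(res$ensemble, cfg)
grp$majority
#> <group_comparison> Mann-Whitney U: statistic 324, p = 2.982e-05 (significant at 0.05)
#>   means: 104.48 vs 88.19; sds: 7.49 vs 15.11
```

(the Shapiro–Wilk gate routed this particular cohort draw to the
Mann–Whitney test; draws compatible with normality go through the unpaired
Student's t instead).

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/triseg.R", package = "triseg"))')" \
    pipeline --out run1 --seed 1 --verbose
```

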