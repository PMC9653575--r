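---
title: "Automated MTV from PET/CT: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated MTV from PET/CT: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents what `petmtv` computes, every numerical choice it
makes (with units, defaults, and rationale), the design of the synthetic
phantom generator, and the decisions that were left open by the method
description and how this implementation resolves them.

## The measurement

Metabolic tumor volume (MTV, cm³) is the total volume of lesion voxels
whose standardized uptake value (SUV) exceeds a threshold tied to the
hottest lesion. The automated pipeline is:

1. segment the five physiologically avid organs (brain, heart, left/right
   kidney, bladder) on CT;
2. adapt those contours to the PET tracer distribution;
3. exclude the adapted organs from the PET volume, and build a trapezoid
   exclusion zone for urinary (ureter) activity;
4. iteratively threshold the remaining volume at 41% of its SUVmax,
   cluster, screen, and sum retained lesion volumes.

## Imaging core

* **Grids and volumes.** A `voxel_grid(shape, spacing_mm, origin_mm)`
  defines voxel centers in world millimeters; `image_volume` and
  `binary_mask` carry values on a grid. All volumes in one case share world
  coordinates, not necessarily one grid (CT is finer than PET).
* **SUV.** `to_suv(activity, injected_dose_bq, body_weight_g)` applies the
  body-weight normalization `SUV = activity * weight / dose`.
* **Resampling.** `resample_mask` / `resample_volume` use nearest-neighbor
  assignment in world coordinates. Rationale: masks must stay binary, and
  the CT→PET transfer step re-derives boundaries from PET intensities
  anyway. Disjoint physical extents are an error.
* **Morphology.** `dilate_mask` / `erode_mask` take radii in millimeters
  and use the exact Euclidean ball on the grid's (possibly anisotropic)
  spacing.
* **I/O.** NIfTI via RNifti (spacing in `pixdim`, origin in the sform/
  qform); organ sets as one label map (1 = brain, 2 = heart, 3 = left
  kidney, 4 = right kidney, 5 = bladder).

## Synthetic phantom generator

`phantom_spec()` + `generate_phantom()` produce a paired CT/PET case with
exact ground truth; `generate_cohort()` draws per-case lesion
configurations and jittered organ geometry.

Design points:

* **Ground truth is pre-blur, pre-noise.** Truth masks and `truth_mtv_cm3`
  are the clean voxelizations; PSF blur (Gaussian, FWHM in mm) and additive
  Gaussian noise are applied afterwards. The acceptance surface needs an
  unambiguous truth, and blur models the scanner, not anatomy.
* **Geometry.** Ellipsoidal organs, spherical lesions, capsule-shaped
  ureter streaks: sufficient for zone logic, contour transfer and
  segmentation; anatomical realism beyond that is a non-goal.
* **Body envelope.** A head ellipsoid, neck capsule, and torso ellipsoid of
  soft tissue (30 HU, SUV 1) surrounded by air (-100 HU, SUV 0.05). The
  envelope exists because the network normalizes each volume; without a
  body outline the normalization erases the only cues that distinguish
  organ from background.
* **Context tissues** (default on): a skull shell (800 HU) around the
  brain, lungs (-750 HU) flanking the heart, fat capsules (-90 HU) around
  kidneys and bladder. Real CT organ segmentation rests on these
  high-contrast interfaces; with uniform soft tissue the synthetic task is
  categorically harder than the real one (organ-vs-tissue contrast of
  10-25 HU against 10 HU noise). Context tissues are painted before the
  organs and never alter ground truth.
* **Default uptakes** (SUV): brain 7, heart 5, kidneys 6, bladder 6,
  ureter 4, background 1; lesions exceed background by construction.
  Values are in the range of typical FDG physiology and, importantly for
  the method, all well above the 41% threshold of typical lesions.
* **Known limitations.** Uniform uptake per structure; no respiratory
  motion, no bone marrow or liver; lesion placement avoids organs and (by
  default) the urinary corridor so that truth MTV is unambiguous.

## Organ segmentation

A 2D dilated residual U-Net implemented from scratch in RcppArmadillo
(`src/unet.cpp`): five encoder and five decoder residual cascades (two 3×3
convolutions, batch normalization, identity or 1×1-projection shortcut),
2×2 max-pool downsampling, bilinear upsampling (half-pixel convention),
skip concatenation, and a 1×1 output convolution to 6 classes.

* **Dilation** defaults to 1 at all levels; the architecture name includes
  "dilated" but rates are unspecified in the method description, so a
  `dilated_bottleneck` preset (rates 1,1,1,2,4) is offered instead of a
  fixed choice.
* **Normalization with batch size 1.** Training is slice-wise with batch
  size 1, so batch statistics equal instance statistics. The layers
  therefore normalize with the current input's statistics in both training
  and evaluation (running means/variances are kept as diagnostics only).
  Using running statistics at evaluation collapses predictions, because
  air-only and organ-bearing slices have very different per-channel
  statistics that a single running average cannot summarize.
* **Preprocessing.** `preprocess_ct` shifts to non-negative values, clips
  to 1-99% *of the maximum* (the literal reading of the method; a
  `"percentile"` mode clipping at the 1st/99th percentiles is provided as
  an option), and Z-score-standardizes the volume.
* **Loss.** `w·CE + (1-w)·(1 - softDice)` with `w = 0.5`. The soft Dice is
  averaged over the foreground classes *present in the slice*; including
  absent classes (with the usual +1 smoothing) gives each a ~1000× stronger
  push-to-zero gradient than cross-entropy provides in the other
  direction, and makes the all-background prediction a stable optimum.
  Cross-entropy alone penalizes false positives of absent classes.
* **Optimization.** Adam (β 0.9/0.999) with decoupled weight decay 1e-4;
  learning rate decayed geometrically to 1% of its initial value over the
  last 40% of epochs (the reference schedule runs 3e-4 → 3e-6 over 100
  epochs). Augmentation: rotation ±10°, translation ±8 mm, scale 0.9-1.1,
  left-right flip with probability 0.5 (which also swaps the kidney
  labels).
* **Fine-tuning.** `fine_tune()` re-initializes the output layer and trains
  either everything or only that layer. The reference description of
  "165 trainable parameters" for adaptation is treated as non-normative
  (implausibly small for a convolution layer); the trainable-scope flag
  replaces it.
* **Inference.** Per-slice argmax restacked to 3D; postprocessing keeps the
  largest 26-connected component of brain/heart/bladder and splits the
  pooled kidney classes into the two largest components assigned
  left/right by x-centroid.

## Contour transfer (CT → PET)

For each organ: resample the CT contour to the PET grid; threshold at 50%
of the 95th percentile of SUV inside the resampled contour; seed with the
4 mm erosion of the contour (intersected with the threshold); grow
26-connected within the contour dilated by a 12 mm safety margin. An organ
with no suprathreshold seeds falls back to the resampled contour with a
warning (e.g., a truly cold organ). Contested voxels between organs are
assigned to the organ where the voxel's SUV is largest relative to that
organ's 95th percentile. A `fast_marching` mode grows by lowest
accumulated cost (distance weighted by inverse local uptake) instead of
plain region growing and gives identical results on clean scenes.

The analysis space is the whole PET volume minus the union of adapted
organs (optionally also voxels below a body threshold).

## Exclusion zone and MTV engine

* **Trapezoid zone.** From the adapted organ masks: the top plane is the
  most superior kidney voxel, the bottom plane the bladder's z-centroid
  slice (rounded). The top base spans between the kidney x-centroids and
  the kidneys' combined y-extent; the bottom base is the bladder's bounding
  box in its central slice; bounds interpolate linearly in between.
* **MTV loop** (`compute_mtv`, defaults in `mtv_params()`): threshold
  `0.41 × SUVmax` (inclusive ≥) over the current analysis space;
  26-connected clustering; clusters >1 cm³ are candidates; candidates
  <2 cm³ are screened (`screened_small`), as are candidates with more than
  half their volume inside the zone (`screened_zone`; `any_overlap` and
  `centroid` rules are provided as options). If the cluster containing the
  current SUVmax is screened or not a candidate, its voxels are removed
  from the space and the loop repeats. Reported `suvmax` is the maximum
  over retained lesions; the first-iteration global maximum is kept as
  `global_suvmax`. Ties for SUVmax resolve to the smallest linear index.
  The full per-iteration trace (thresholds, cluster statuses) is returned.

## Agreement statistics

`pearson_correlation` (with `cor.test` CI), `icc_agreement` — the two-way
random-effects, single-measure, absolute-agreement ICC (McGraw & Wong's
ICC(A,1)) with the F-based confidence interval — `bland_altman`
(differences are reference − method; limits ±1.96 SD), `rmse_and_bias`
(positive bias = mean positive difference, negative bias = mean magnitude
of negative differences; 0 when a side is empty), and
`coefficient_of_variation` (100·SD/mean, sample SD; `cv_from_moments` for
printed moments). The ICC implementation was cross-checked to 12 digits
against an independent reference implementation at development time.

## Fixed study protocols

* `segmentation_protocol()`: 50 phantoms (cohort data seed 7) on a
  96×96×64 grid at (4, 4, 10) mm with 10 HU CT noise, 5:1:4
  train/validation/test split, 8 foreground + 2 background slices per
  volume per epoch. The network and schedule are scaled to desk hardware
  (see the protocol object for the frozen width/epochs/learning rate).
* `cohort_protocol()`: 100 phantoms with 4 mm FWHM blur and 0.1 SUV noise
  for the MTV agreement study.

The protocols are frozen so the test suite and the acceptance script
exercise identical conditions; `segmentation_benchmark()` and
`cohort_benchmark()` run them.

## Open decisions and their resolutions

| Open point | Resolution |
|---|---|
| Dilation rates unspecified | default 1; optional dilated-bottleneck preset (1,1,1,2,4) |
| "1-99% of the maximum" clipping | implemented literally; percentile mode as an option |
| "165 trainable parameters" for adaptation | non-normative; trainable-scope flag instead |
| Dice averaging over classes | present-classes-only (absent classes would make collapse optimal) |
| ICC variant unnamed | two-way single-measure absolute agreement, ICC(A,1) |
| Positive/negative "bias" definitions | one-sided means of signed differences (see `rmse_and_bias`) |
| Zone membership rule | majority (>50% in zone); any-overlap and centroid variants available |
| Problem sizes | scaled-down synthetic surrogates; published real-data Dice/agreement values are floors for the surrogate, not reproduction targets |

```{r}
library(petmtv)
spec <- phantom_spec(blur_fwhm_mm = 4, noise_sd_suv = 0.1,
                     lesions = list(lesion_spec(c(150, 160, 360), 15, 9)))
case <- generate_phantom(spec, seed = 1)
res <- run_pipeline(case$pet, organs = case$truth_organs)
print(res$mtv)
validate_against_truth(res, case)
```
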