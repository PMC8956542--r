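---
title: "Cascaded two-stage cardiac contouring: models, phantoms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded two-stage cardiac contouring: models, phantoms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(heartcascade)
```

## The problem

Radiotherapy planning CTs of the thorax are low-dose, non-contrast, and
acquired without ECG triggering. Contouring the heart and its chambers
(whole heart WH, left/right ventricle LV/RV, left/right atrium LA/RA) on
such scans is clinically valuable — for sparing the heart during breast
irradiation and as a mask for downstream tasks such as coronary calcium
scoring — but the chamber boundaries are genuinely low-contrast: blood pool
and myocardium differ by only a few HU, and the heart occupies a small
fraction of the axial slices.

This package implements a cascaded two-stage 2.5D pipeline for that
problem:

1. **Stage 1 — slice gating.** A compact residual convolutional classifier
   labels every axial slice as heart / no-heart. Restricting stage 2 to the
   gated slab removes most of the class imbalance between heart and
   non-heart voxels.
2. **Stage 2 — three-plane segmentation.** Three fully convolutional
   networks with *full-scale skip connections* run in parallel: one
   segments all five structures on axial slices; the other two segment only
   the whole heart on coronal and sagittal slices, sharpening the cranial
   and caudal boundaries that per-slice axial networks get wrong.
3. **Fusion.** The three views are binarised at 0.5 and combined by
   voxel-wise multiplication (conjunction) of the binary masks.

Training uses Adamax throughout: binary cross-entropy for stage 1 (early
stopping on the tuning-set F1 with heart as the positive class), and for
stage 2 the hybrid objective

$$L_\mathrm{hybrid} = 2\,L_\mathrm{focal} + L_\mathrm{dice},$$

with the focal term weighted twice, early stopping on tuning-set mean Dice.

## Networks and the training engine

No deep-learning framework is available to this package, so it ships a
small reverse-mode automatic differentiation engine (`R/nn.R`): feature
maps are `(H*W) x C` matrices, convolutions are an `im2col` gather
(compiled code) followed by one BLAS matrix product, and a tape replays
each forward pass backwards for gradients. Adamax is implemented as
published (`beta1` 0.9, `beta2` 0.999, `epsilon` 1e-7). Everything runs on
one CPU; seeded runs are bit-reproducible at a fixed BLAS thread count
(set `OPENBLAS_NUM_THREADS=1` for strict single-thread determinism).

Two backbones satisfy the stage-1 contract. The desk-scale
`compact_residual` network (stem convolution, three residual blocks with
max-pooling, concatenated global average + log-sum-exp pooling, sigmoid
unit) trains in minutes. `inception_resnet_v2` names the clinical-scale
backbone; it requires externally supplied pretrained weights and is
deliberately not bundled, so selecting it raises an informative error.

The stage-2 networks follow the full-scale-skip design: decoder level $d$
aggregates rescaled features from *every* encoder level at the same or
finer scale (mean-pooled down) and every coarser decoder including the
bottleneck (nearest-neighbour upsampled), so each decoder level receives
exactly `depth` streams; each stream passes a 3x3 convolution to
`base_channels` channels, and the concatenation is fused by a 3x3
convolution. Deep supervision (auxiliary heads on coarser decoders) is
implemented but off by default — the cascade design statement does not use
it.

Segmentation-network convolutions are followed by **instance
normalisation** (per-slice, per-channel standardisation with learned gain
and shift) before the ReLU. This is the decisive stabiliser at desk scale:
without normalisation the sigmoid outputs of the small-structure channels
(the atria especially) saturate toward zero early in training and the
vanishing sigmoid gradient never recovers them. Instance normalisation is
the standard choice for segmentation networks trained with small batches;
it needs no running statistics, so inference is deterministic and
batch-independent. The *classifier*, by contrast, runs without
normalisation: the absolute windowed intensity level is itself evidence
for heart presence, and per-slice contrast stretching amplifies noise on
heart-free slices (measurably more liver false positives). Both choices
are exposed as the `normalization` config field.

## The synthetic phantom

The clinical dataset the pipeline was designed for (50 planning CTs with
expert contours) is private, so the package generates synthetic thoracic
phantoms that reproduce the *statistical structure* the pipeline assumes:

- a torso with two low-HU lungs (default −780 HU, far below the
  mediastinum window floor of −125 HU);
- a heart modelled as a tilted ellipsoid (axial rotation −25°, sagittal
  tilt 20°), partitioned into four chamber sub-ellipsoids with the atria
  cranial to and smaller than the ventricles; myocardium and chamber mean
  HU all lie within 10 HU of each other (WH 45, LV 50, RV 40, LA 48,
  RA 42), reproducing the low-contrast ambiguity of non-contrast CT;
- a liver ellipsoid abutting the caudal heart boundary at 60 HU — within
  30 HU of the heart — so the hardest clinical confusion (heart apex vs
  liver) is present, including caudal slices that contain liver but no
  heart;
- per-voxel Gaussian noise, default 20 HU, a realistic figure for low-dose
  chest CT soft tissue;
- slice thickness 3 or 5 mm, mixed in the 29:21 ratio of the emulated
  acquisition protocol; per-volume heart size (±10%) and centre jitter
  (±4 mm).

The default desk grid is 64 × 96 × 96 voxels at 1 mm in-plane — chosen for
CPU tractability — with `phantom_config_clinical()` providing the 512 × 512,
500 mm field-of-view clinical geometry for shape checks. A single global
seed drives everything; per-volume seeds derive from it by two fixed
rounds of the MINSTD linear congruential map, so a dataset is reproducible
as a whole and per volume.

What the phantom deliberately does **not** model: myocardial wall
thickness variation, contrast enhancement, respiratory or cardiac motion,
scanner artefacts, and anatomical shape variability beyond affine size and
position changes. Passing the synthetic recovery tests therefore
demonstrates that the pipeline's machinery — gating, training, fusion,
metrics — works end-to-end on data with the right contrast structure; it
does not certify clinical accuracy on real patients.

## Desk-scale study conditions

The reference desk study (used by the acceptance script and the recovery
tests, `run_desk_study()`) generates 16 phantoms: 10 training, 3 tuning,
3 validation — scaled down from the emulated protocol's 44/3/3 split
(keeping its three tuning volumes),
whose bookkeeping (including the stage-2 re-split that moves three
thin-slice volumes from training to validation, 44/3/3 → 41/3/6) is
implemented and tested at manifest level. Stage 2 trains on the first
five training volumes; stage 1 uses all ten (slice classification needs
many volumes more than the segmenters need many slices).

Training settings at desk scale (all configurable,
`desk_training_configs()`):

- Stage 1: slices mean-pooled to 48 × 48, base width 8, batch 15, Adamax
  learning rate 1e-2 decayed by 0.8 per epoch, at most 14 epochs,
  patience 7, no normalisation.
  Slices within two slices of the cranial/caudal heart boundary are
  oversampled three extra times — the same class-imbalance device as the
  protocol's added liver-only slices — because boundary caps and the
  adjacent liver slices are the classifier's only hard cases.
- Stage 2 axial (five channels): depth 3, base width 8, fuse width 16,
  batch 5, learning rate 2e-3, at most 16 epochs, patience 8; every second
  heart slice plus three liver-only slices per volume.
- Stage 2 coronal/sagittal (WH only): base width 6, fuse width 12, at most
  8 epochs; every fourth slab slice. These planes are trained and applied
  on the slab-cropped volume, z-resampled to the in-plane resolution
  (linear for intensities, nearest-neighbour for masks).

The clinical-scale defaults (`classifier_config()`, `segmenter_config()`)
keep the published values: batch 15 / learning rate 1e-4 / 50 epochs for
stage 1; batch 5 / learning rate 1e-3 / beta1 0.9 / beta2 0.999 /
epsilon 1e-7 for stage 2. The published learning rates are written
"10e-4"/"10e-3", which read literally would be 1e-3/1e-2; they are
interpreted as the conventional 1e-4/1e-3. The published stage-1 run also
reports early stopping "after 89 epochs" with a 50-epoch maximum; the
implementation honours `max_epochs` and treats the 89 as an inconsistency
in the source description.

## Numerical and design choices

- **Windowing** maps HU affinely to [0, 1] with the mediastinum window
  (width 350, level 50); the level maps to 0.5, values at or below −125 HU
  clamp to 0, at or above 225 HU to 1.
- **Slab smoothing**: single-slice gaps in the positive run are closed and
  the longest contiguous run is kept (ties: most cranial). Rationale: the
  known failure mode is a single misclassified boundary slice; gaps of two
  or more slices are evidence against a contiguous heart and are not
  bridged.
- **Fusion rule**: the final WH mask is axialWH ∧ coronalWH ∧ sagittalWH.
  Substructure masks are gated by coronalWH ∧ sagittalWH but *not* by the
  axial WH channel (the source description is ambiguous); the stricter
  variant is available via `gate_substructures_by_axial_wh = TRUE`. The
  default preserves the stated purpose of the extra planes — fixing the
  cranial/caudal boundary — without letting an axial WH error veto a
  correct chamber prediction.
- **Thresholds**: 0.5 for the stage-1 decision and for all mask
  binarisation; both configurable (lowering the stage-1 threshold trades
  false negatives, the clinically stated concern, against
  oversegmentation).
- **HD95**: boundary voxels are mask voxels with at least one
  face-adjacent background neighbour (array edges count as background);
  directed distances are computed in physical mm between boundary voxel
  centres; the 95th percentile is nearest-rank; the symmetric value is the
  maximum of the two directed percentiles. Empty masks yield `NA`
  ("missing"), never 0.
- **Dice conventions**: both-empty = 1, empty-vs-non-empty = 0.
- **Volume ratio** is predicted/manual. The source text says "ratio
  between the manual and predicted volumes" but its own results (atria
  reported *under*-segmented with ratios < 1) only make sense as
  predicted/manual; the direction is therefore fixed as predicted/manual
  and documented here.
- **Quantiles** in report tables use the linear-interpolation definition
  (R type 7).
- **Focal loss** parameters are not specified in the source; the defaults
  gamma = 2, alpha = 0.25 follow the originating focal-loss literature,
  with alpha applied as a constant factor (the "weighted twice" of the
  hybrid objective is an outer factor on the whole focal term).
  Probabilities are clipped to [1e-7, 1 − 1e-7]; dice smoothing is 1e-6.
- **Multi-channel reduction**: unweighted mean over structure channels.
- **Coordinate conventions**: arrays are (z, y, x), z increasing caudally,
  0-based slice indices in all user-facing records.
- **z-resampling for the coronal/sagittal planes** is a documented
  decision, not a source fact: at 3–5 mm slices an unresampled coronal
  image would be distorted ~3–5:1, so the volume is resampled along z to
  the in-plane spacing before reslicing, and predictions are mapped back
  by nearest neighbour. The round-trip preserves the WH mask to Dice
  ≥ 0.95 and its volume to within 5% on default phantoms (tested).
- **Gated-slab cropping for the coronal/sagittal networks**: whether the
  original design fed these networks the full cranio-caudal extent is
  unstated; the gated slab is used (training uses the ground-truth heart
  z-range, inference the classifier's slab), which keeps the two planes'
  task aligned with the gating stage.

## Known limitations

- Desk-scale networks on synthetic phantoms recover the whole heart
  reliably; the chambers — in particular the atria, whose per-pixel
  contrast against myocardium is far below the noise floor — are
  recovered only partially. This mirrors, in exaggerated form, the
  atrial under-segmentation documented for the clinical pipeline; the
  per-structure tables produced by the evaluation code make the gap
  visible rather than hiding it.
- The published headline accuracies (median WH Dice 0.96, HD95 1.86 mm on
  private clinical data with GPU-scale training) are out of reach of this
  desk-scale artifact by design; the acceptance machinery instead checks
  exact worked examples, oracle equivalence of every metric, the loss
  identity, fusion algebra, and seeded recovery thresholds on phantoms.
- DICOM support is read-only and minimal: explicit-VR little-endian,
  uncompressed, axial axis-aligned series; oblique acquisitions and
  implicit-VR files are rejected with clear errors. NIfTI is the
  canonical format.
- Training is single-threaded by design for reproducibility; there is no
  augmentation (the emulated protocol used none) and no test-time
  ensembling beyond the three stated views.
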