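---
title: "Image-space correction of bone-blind PET/MR attenuation correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-space correction of bone-blind PET/MR attenuation correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(petcorr)
```

## The problem

Quantitative PET requires attenuation correction (AC): every line of
response must be compensated for the photons lost to absorption and
scatter along it, using a map of linear attenuation coefficients (LAC,
cm^-1^) at 511 keV. On PET/CT the LAC map comes from the CT itself. On
PET/MR there is no direct handle on electron density, and the standard
clinical fallback — four-class Dixon-based AC — segments the Dixon MR pair
into air, lung, fat and soft tissue and assigns each class a fixed LAC.
Cortical bone has almost no MR signal (its T2* is too short), so bone is
silently labelled soft tissue. Bone attenuates far more than soft tissue,
and the result is a systematic underestimation of activity in and near
bone — exactly where skeletal metastases of prostate cancer sit.

`petcorr` implements an image-space remedy: rather than building a better
mu-map and re-reconstructing, it predicts the voxel-wise *error* of the
four-class reconstruction and inverts it after the fact.

## The correction map

Let `PET_4C` be the reconstruction with the four-class mu-map and
`PET_CT+MR` the reference reconstruction whose mu-map uses the same
Dixon-derived soft-tissue classes plus bone transferred from a
co-registered CT. The correction map is

    C = (PET_4C - PET_CT+MR) / PET_4C

so that `PET_CT+MR = PET_4C * (1 - C)` exactly. `compute_correction_map()`
and `apply_correction_map()` implement the two directions; the algebraic
closure (apply after compute returns the reference to machine precision) is
property-tested. A convolutional network (`build_network()`,
`train_network()`) learns slice-wise `C` from three channels — Dixon
in-phase, Dixon out-of-phase and the four-class mu-map — and
`predict_correction_map()` applies it to unseen subjects, yielding the
corrected image `PET_cor` without any re-reconstruction.

Two numerical guards surround the definition:

* **Activity floor.** `C` is a ratio and meaningless where `PET_4C` is
  close to zero. It is only defined where the pelvic mask holds and
  `PET_4C >= floor_bqml` (default 300 Bq/ml, the same threshold the voxel
  metrics use); elsewhere it is exactly 0 and excluded from the valid
  mask.
* **Clamp range.** Predicted maps are clamped to `[-2, 1]` before
  application and the corrected image is clamped at 0, so no single
  prediction can more than triple or fully null a voxel. Training targets
  are clamped to the same range: in the synthetic phantoms the exact map
  reaches values far below -2 in deep-bone voxels whose `PET_4C` sits just
  above the floor, and an unclamped L2 loss would be dominated by
  corrections the applied map can never express.

## The synthetic study

The clinical datasets this method was designed for are not redistributable,
so the package carries its own cohort generator and scanner stand-in; every
stage downstream of them also accepts user-supplied co-registered NIfTI
volumes.

### Phantoms (`phantom_spec()`, `generate_phantom()`)

One phantom plays the role of one patient's co-registered CT + Dixon + PET
session: an elliptical body with a subcutaneous fat ring, two to five bone
structures (cortical shells around marrow), and spherical lesions with a
known lesion-to-background activity ratio (default 4:1 over a 5000 Bq/ml
background). CT values are drawn per class (air -1000; fat -120..-80;
soft tissue 20..60; marrow 100..300; cortical bone 700..1500 HU); Dixon
intensities are class-conditional draws in which fat and marrow are bright
in-phase and dark out-of-phase, soft tissue is bright in both, and cortical
bone and air are near zero. Anatomy varies smoothly along z — the body
tapers, bones drift and change calibre — so each axial slice presents a
distinct geometry, as in real pelvic data; this matters because the network
is trained on 2D slices. All randomness derives from one seed and phantoms
are bit-reproducible.

What the generator deliberately does *not* emulate: MR coil bias fields,
motion, metal, Dixon fat/water physics (the intensities only need to make
the classes separable), lungs (pelvic field of view), and anatomically
shaped bones. Passing tests therefore demonstrate that the pipeline
recovers the bone-omission error it simulates, not clinical performance.

### Mu-maps (`phantom_mumaps()`)

The four-class map thresholds the fat fraction proxy `(IP - OP) / (2 IP)`
inside the body contour and assigns fat 0.0854, soft tissue 0.1000, air
0 cm^-1. With magnitude MR images the proxy is bounded above by 0.5 (fat
sits near 0.4, water-dominated tissue near 0), so the decision threshold
defaults to 0.25, the midpoint of the separable gap. The body contour is an
Otsu split of the in-phase histogram followed by per-slice hole filling and
largest-component selection — hole filling is what keeps signal-free bone
interiors inside the body.

The reference map starts from the four-class map and overwrites every voxel
whose CT-derived LAC exceeds 0.1 cm^-1 (within the pelvic mask) with that
CT value — full CT LACs are transferred, not just the increment over soft
tissue. The CT is scaled by the bilinear 511 keV transform
(`hu_lac_transform()`): water-line below 0 HU, reduced slope
5.64 x 10^-5 cm^-1 per HU above; the constants belong to the standard
calibration family and are configurable, not literature-prescribed to this
dataset.

### PET simulator (`forward_project()`, `reconstruct()`)

A deliberately simple slice-wise 2D parallel-beam chain: attenuated line
integrals of the activity (path lengths in cm against the *reference*
mu-map), optional Poisson noise at a configurable expected count level, and
ordered-subset EM reconstruction in which attenuation enters as per-line
multiplicative factors from whichever mu-map the caller supplies. The
mu-map mismatch between forward projection and reconstruction is the object
of study. Defaults: 3 iterations, 21 subsets, 126 angles (divisible by the
subset count), a 4 mm Gaussian post-reconstruction filter, interleaved
subset angles, and a system matrix built by half-pixel ray sampling with
bilinear splatting (point sources project accurately; a matched noiseless
reconstruction recovers a uniform disc's mean within a fraction of a
percent). Scatter, randoms, PSF modelling and time-of-flight are out of
scope. One subset gives plain MLEM; voxels with zero sensitivity are
excluded from updates rather than divided by zero.

With 6 mm voxels and cortical shells a few voxels thick, every in-plane
line of response through a bone voxel crosses bone, so the simulated
underestimation inside bone is deeper than clinically reported pelvic
errors; the error *direction* and spatial structure are the properties
the package asserts.

### Network (`net_config()`, `build_network()`)

A 2D residual encoder-decoder in the image-to-image generator family: a
7x7 full-resolution convolution, two stride-2 downsampling convolutions
(to one-fourth resolution), a stack of residual blocks (instance
normalisation inside), a mirrored transposed-convolution back-end, and a
3x3 linear output convolution (correction values are signed, so there is
no saturating output activation). The full-size configuration is 9 blocks
with 64 base filters; tests and the desk-scale study use 1-3 blocks with
16 filters. Implementation is pure R + BLAS (im2col convolutions with
C-level gather/scatter); gradients are verified against central finite
differences in the test suite.

Training: Adam on the masked L2 loss — mean squared error over valid-mask
voxels only, so values outside the mask neither contribute nor bias the
network toward zero at mask borders. The learning rate is constant for the
first half of training and decays linearly to zero afterwards (the
schedule is unit-tested at its corner points). Inputs are min-max scaled
to [0, 1] per volume (not per slice, preserving inter-slice intensity
relations; per-channel, since the mu-map's range is physical) and zeroed
outside the body contour. Base learning rate 2e-4 (1e-3 in the reduced
desk-scale setting), batch 16 (8 reduced) — package choices, as are the
kernel sizes. No data augmentation is applied.

### Metrics and statistics (`compute_metrics()`, `lesion_metrics()`)

The relative-error image against the reference is
`RE = (I - I_ref) / I_ref`, evaluated only inside the pelvic mask at voxels
whose reference activity exceeds 300 Bq/ml (thresholding on the reference
keeps the evaluable set identical across compared methods). Summary
metrics: `MAPE = 100 mean(|RE|)` and `RMSPE = 100 sqrt(mu^2 + sigma^2)`
with the *population* variance, which makes
`RMSPE = 100 sqrt(mean(RE^2))` an exact identity (asserted in tests) and
guarantees `RMSPE >= MAPE`. Lesion quantification uses SUV~max~ over the
full lesion ROI (the SUV scale constants cancel in all relative errors).
Paired method comparisons use the two-sided Wilcoxon signed-rank test with
Benjamini-Hochberg adjustment across families of comparisons; unpaired
group comparisons (e.g. between tracer analogues) use the Mann-Whitney U
test; significance at p < 0.05. Reports are formatted as median [min, max].

## Problem sizes

The test suite and the acceptance script run the study at desk scale,
chosen so the whole pipeline remains exercised end to end: phantoms on a
64 x 64 x 32 grid of 6 mm voxels; 8 training, 2 validation and 4 test
phantoms (about 200 training slices); a reduced network (3 residual
blocks, 16 base filters) trained for 24 epochs with decay from epoch 12.
Unit tests use 32-48 voxel grids and 1-block networks.

## Known limitations

* The simulator is 2D and noise-idealised; its bone-omission bias is
  stronger than clinical pelvic errors, and no claim about clinical error
  magnitudes follows from the synthetic study.
* Lesions are visible only in the activity map, not in CT/MR, mirroring
  the fact that the network cannot see uptake; in very deep bone the
  clamped correction can overshoot at lesion sites whose true local error
  is smaller than their surroundings'. The lesion tables the package
  writes make this visible rather than hiding it.
* The learned model transfers only to data resembling its training
  distribution; a clinical deployment would retrain on clinical pairs.
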