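# petcorr

Image-space correction of the bone-omission error in four-class
Dixon-based PET/MR attenuation correction, with a complete synthetic
pelvic evaluation pipeline.

## The problem

Whole-body PET/MR attenuation correction (AC) is usually derived from
Dixon MR: the body is segmented into air, lung, fat and soft tissue, and
each class receives a fixed linear attenuation coefficient (LAC) at
511 keV. Cortical bone has almost no MR signal and is classified as soft
tissue, so activity in and near bone — where skeletal metastases of
prostate cancer are common — is systematically underestimated.

`petcorr` implements a post-hoc remedy: predict the voxel-wise error of
the four-class reconstruction directly in the image space and invert it,
with no re-reconstruction. Writing `PET_4C` for the four-class
reconstruction and `PET_CT+MR` for the reference reconstruction (Dixon
soft tissue + CT-derived bone), the correction map is

```
C = (PET_4C − PET_CT+MR) / PET_4C        so that   PET_CT+MR = PET_4C · (1 − C)
```

A residual encoder–decoder network learns `C` slice-wise from three
channels (Dixon in-phase, Dixon out-of-phase, four-class µ-map); applying
the predicted map to `PET_4C` yields the corrected image `PET_cor`.
Performance is measured by the relative-error image
`RE = (I − I_ref)/I_ref` summarized as `MAPE = 100·mean(|RE|)` and
`RMSPE = 100·sqrt(µ_RE² + σ_RE²)` over the pelvic mask (voxels with
reference activity > 300 Bq/ml), by lesion `SUV_max` errors, and by
Wilcoxon signed-rank / Mann–Whitney U comparisons with
Benjamini–Hochberg adjustment.

Because clinical PET/MR+CT datasets are not redistributable, the package
contains every stage needed to reproduce the methodology end to end on
synthetic data: a randomized pelvic phantom generator, four-class and
reference µ-map construction (bilinear HU→LAC scaling, CT bone insertion
above 0.1 cm⁻¹ within a pelvic mask), a 2D attenuated-projection OSEM
simulator (3 iterations × 21 subsets, 4-mm Gaussian post-filter) that
reproduces the bone-omission bias, the network (pure R + BLAS, gradients
verified against finite differences), and the evaluation statistics. All
stages also accept user-supplied co-registered NIfTI volumes.

## Worked example

```r
library(petcorr)

ph  <- generate_phantom(phantom_spec(seed = 42))     # one synthetic patient
mm  <- phantom_mumaps(ph)                            # four-class + reference mu-maps
pets <- simulate_pet_pair(ph, mm$mu4c, mm$muref, recon_config())

# how wrong is the four-class reconstruction?
re <- relative_error_image(pets$pet_4c, pets$pet_ctmr, ph$pelvic_mask)
compute_metrics(re)
#> MAPE 11.81%  RMSPE 24.27%  (mu -0.0916, sigma 0.2248, n=46184)

# the exact correction map inverts the error wherever it is defined
cmap <- compute_correction_map(pets$pet_4c, pets$pet_ctmr, ph$pelvic_mask)
petfix <- apply_correction_map(pets$pet_4c, cmap)
compute_metrics(relative_error_image(petfix, pets$pet_ctmr, ph$pelvic_mask))
#> MAPE 0.00%  RMSPE 0.62%  (mu -0.0000, sigma 0.0062, n=46184)
```

The numbers say: omitting bone inflates the voxel-wise error to an RMSPE
of ~24 % over the pelvic mask (mean relative error −9 %, a net
underestimation), and the correction-map algebra removes it to machine
precision wherever the map is defined (the residual 0.6 % lives in voxels
below the 300 Bq/ml activity floor, where the map is deliberately left
at zero). The learned model recovers a large fraction of
this ideal correction on phantoms it has never seen; run the experiment
pipeline to measure it:

```r
cfg <- experiment_config(
  net = net_config(n_resblocks = 3, base_filters = 16, epochs = 24,
                   decay_start = 12, lr = 1e-3, batch_size = 8),
  n_train = 8, n_val = 2, n_test = 4, seed = 1)
res <- run_experiment(cfg, "run1")        # writes NIfTI + CSV + JSON artifacts
res$summary$voxel
```

A command-line front end over the same functions is installed at
`inst/cli/petcorr` (`petcorr phantom|mumap|simulate|correct|evaluate|run`).

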