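Package: petcorr
Title: Image-Space Bone Correction for Four-Class Dixon PET/MR Attenuation Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying and correcting the quantification error that
    four-class Dixon-based attenuation correction introduces in pelvic PET/MR
    by ignoring bone. Provides randomized synthetic pelvic phantoms, four-class
    and reference (soft tissue plus CT bone) mu-map construction, a slice-wise
    attenuated-projection OSEM simulator that reproduces the bone-omission
    bias, the voxel-wise correction-map algebra, a residual encoder-decoder
    network trained to predict correction maps from Dixon MR and the four-class
    mu-map, and voxel- and lesion-level error metrics (MAPE, RMSPE, SUVmax)
    with nonparametric comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
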