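Package: slabimpute
Title: Isotropic Slice Imputation for Anisotropic Brain Slab Reconstructions
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: Converts anisotropic 3D reconstructions of brain dissection
    photographs (thick, possibly unevenly spaced coronal slabs) into 1 mm
    isotropic volumes by imputing the missing coronal slices. A 2D U-Net,
    conditioned on the two bounding observed slices and their distances to
    the target coordinate, predicts the residual relative to linear
    interpolation. The network is trained entirely on domain-randomized
    synthetic data generated on the fly from 3D label maps (random affine and
    nonlinear deformation, label-conditioned Gaussian intensity synthesis,
    gamma augmentation, multiplicative illumination fields, random digital
    slabbing). Also provides volume-level inference at arbitrary slice
    spacing, procedural brain phantoms, and evaluation metrics (region-wise
    Dice, closest-point surface distance, cortical thickness error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
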