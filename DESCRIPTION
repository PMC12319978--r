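Package: fetalfilter
Title: Temporal Filtering, Quality Control and Group Fusion for Fetal Multiband fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression-based temporal filtering for in-utero functional MRI
    acquired with sequential multiband (MB) sampling. Implements the three
    groups of deconfounding regressors tailored to fetal data: detrending,
    volume censoring, folding and density maps (spatial-inconsistency
    artefacts); voxel-wise motion-parameter regressor stacks with slice
    differentials and per-voxel PCA reduction plus data-derived non-grey-matter
    ICA time courses (motion-induced signal changes, including spin history);
    and slab-component estimation with partial regression removal (sequential
    MB sampling artefacts). Includes a per-voxel GLM engine, TSNR/DVARS quality
    control with parametric outlier decision rules, a signal-implanting test
    for denoising model selection, age-balanced group ICA with dual regression,
    per-edge age-effect modelling and Laplacian embedding with Ward clustering,
    and a synthetic multiband acquisition generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
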