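Package: dvfsynth
Title: Diffeomorphic Deformation Synthesis of Planning CT from Diagnostic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes a planning-setup thoracic CT from a diagnostic-setup CT by
    predicting a dense deformation vector field with a conditional adversarial
    network and applying it as a guaranteed-diffeomorphic warp, so that every
    synthesized voxel is an interpolated Hounsfield value of the input scan.
    Provides grid-aware volume types with NIfTI input/output, resampling and
    warping, a paired synthetic thoracic phantom generator with analytic
    ground-truth deformations, couch removal and intensity normalization, a
    stationary-velocity-field exponential (scaling and squaring) with Jacobian
    folding diagnostics, the soft-window contrast-fidelity and curvature losses,
    a compact 3D U-Net generator and convolutional discriminator trained with
    manual backpropagation, and RASSD/Dice/Hausdorff evaluation with per-case
    and cohort reports. A command-line interface ties the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
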