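Package: artifactlab
Title: Simulation, Detection and Correction of Respiratory Artifacts in 4DCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for studying phase-binning and interpolation
    artifacts in four-dimensional computed tomography (4DCT) of the lung.
    Provides a seedable multi-phase breathing phantom with paired lung masks,
    analytical generators that infuse phase-binning artifacts (stack blending
    with an admissibility condition) and interpolation artifacts (linear slice
    interpolation over perturbed intervals) together with voxel-level
    ground-truth masks, a rule-based interpolation-artifact detector with
    per-segment thresholds fitted by minimizing Dice loss, a localized
    artifact correction method, multi-level detection metrics (Dice, Youden's
    J, an overfitting index, mesh-based boundary smoothness), and
    artifact-omics morphological feature extraction with Mann-Whitney and
    TOST equivalence testing under FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
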