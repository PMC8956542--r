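Package: heartcascade
Title: Cascaded Two-Stage Contouring of Cardiac Structures on Non-Contrast CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a cascaded two-stage pipeline for
    contouring five cardiac structures (whole heart, left and right ventricle,
    left and right atrium) on low-dose non-contrast planning CT. A slice-level
    classifier first gates the axial slices that contain the heart; three 2D
    fully convolutional segmentation networks (five structures on axial slices,
    whole heart on coronal and sagittal slices) then contour the gated slab and
    are fused into a 3D result by multiplication of the binary masks. Includes
    the hybrid focal+dice training objective, Adamax-based training loops with
    early stopping, evaluation metrics (Dice, 95th-percentile Hausdorff
    distance in mm, volume ratio, Cohen's kappa, accuracy, F1), a synthetic
    thoracic CT phantom generator with ground-truth labels for end-to-end
    testing on one CPU, NIfTI/DICOM volume input, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
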