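Package: portalseg
Title: Portal-Vein Segmentation on Multiphase CT Angiography via Style
    Transfer and Confidence-Weighted Pseudo Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments the portal vein on the unannotated hepatic-arterial (H)
    and equilibrium (E) phases of abdominal CT angiography using only a
    portal-venous (P) phase annotation.  An adversarially trained volumetric
    generator transfers H/E blocks into P-phase intensity style; a 3D U-Net
    is trained jointly under an eight-term objective in which a
    confidence-weighted pseudo label, built each iteration from the
    intersection of the network's own predictions and the P-phase ground
    truth, compensates for inter-phase vessel shift.  Includes volumetric
    preprocessing (CT-bed removal, axial phase alignment, annotation-centered
    block extraction), confusion-count evaluation metrics, a synthetic
    multiphase vascular phantom generator so the whole pipeline is testable
    without clinical data, and a small reverse-mode autodiff engine with
    compiled 3D convolution kernels that the networks are built on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
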