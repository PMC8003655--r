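Package: glioadapt
Title: Facility Adaptation for Glioma MR Segmentation by Selective
    Block Fine-Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying and correcting facility-to-facility domain
    shift in volumetric brain tumor segmentation.  Provides a synthetic
    multi-facility phantom generator for 4-channel MR-like volumes
    (T1, T2, FLAIR, GdT1) with BraTS-style sub-region labels; NIfTI input
    and output, whole-tumor VOI merging, Z-score normalization and
    crop/resize preprocessing; a block-named 3D encoder-decoder
    segmentation network with a registry mapping every learnable
    parameter to a named block; five selective-layer fine-tuning
    strategies including the down2_up2 protocol for adapting a trained
    model to a new facility with 20 or fewer cases; Dice evaluation,
    Welch ANOVA with Games-Howell post-hoc comparison, and a workflow
    driver that reproduces the degradation-and-recovery experiment on
    synthetic facilities at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
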