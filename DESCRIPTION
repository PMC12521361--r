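Package: tibiamorph
Title: Standardized Trabecular Compartment Analysis for Mouse Tibia Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Slice-wise compartment classification and standardized volume-of-interest
    (VOI) extraction for micro-CT scans of the murine proximal tibia. The package
    detects the transitional landmarks between the epiphyseal bone, growth plate,
    primary spongiosa and secondary spongiosa from per-slice class-probability
    profiles, extracts anatomically anchored VOIs, and computes 3D and depth-resolved
    trabecular morphometry (BV/TV, Tb.Th, Tb.Sp) via a fast local-thickness
    algorithm. A synthetic tibia-phantom generator with voxel-level ground truth
    makes the whole pipeline testable without animal data, and a statistics layer
    provides TOST equivalence testing, intraclass correlation, and depth-resolved
    group comparisons with ANOVA, Tukey HSD and Games-Howell post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    png,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    EBImage
Config/testthat/edition: 3
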