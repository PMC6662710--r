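Package: facesym
Title: Mirroring-Based Quantification of Three-Dimensional Facial Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies bilateral asymmetry of craniofacial structures from
    voxel volumes and cephalometric landmarks. Builds the Frankfort
    horizontal, midsagittal, and mandibular median reference planes from
    named landmarks, binarizes Hounsfield-unit volumes, applies 3D
    morphological cleanup (hole filling, spherical closing), splits
    structures into bilateral halves, mirrors one half onto the other, and
    reports the non-overlapping volume and Sorensen-Dice similarity index
    alongside conventional linear, surface, and volume measurements.
    Includes a synthetic mandible phantom generator with parameterized
    asymmetry and a cohort statistics layer (paired t tests, Pearson
    correlation, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
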