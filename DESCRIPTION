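Package: pettex
Title: Robustness of PET Texture Indices to Segmentation and Observer Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how three-dimensional texture indices computed on
    FDG PET tumor volumes respond to the choice of delineation method and to
    inter-observer variability. Provides a synthetic PET phantom cohort
    generator with controllable heterogeneity, partial-volume blur and noise;
    three tumor delineation methods (fixed 40% SUVmax threshold, adaptive
    signal-to-background threshold calibrated on sphere phantoms, and radial
    gradient-edge detection); absolute-resampled gray-level discretization and
    the four standard texture matrices (co-occurrence, run-length,
    neighborhood dependence, zone-length) with 31 derived indices; and the
    agreement statistics used to compare them (Pearson correlation grouping,
    Bland-Altman analysis, Friedman and Wilcoxon tests, and two-way
    random-effects intraclass correlation with Landis-Koch interpretation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
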