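Package: hepavol
Title: Hepatic Vessel Volumetry from 3D Images with a 3D U-Net and Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies hepatic vascular volume from volumetric images. Grows
    synthetic bifurcating portal and hepatic venous trees inside liver phantoms,
    simulates clinical cohorts of chronic liver disease patients with calibrated
    biomarker marginals and rank-correlation structure, segments vessels with a
    compact 3D U-Net trained by patch-based optimisation, derives per-voxel vessel
    calibre with an anisotropic Euclidean distance transform, computes
    vessel-to-volume ratios (TVVR, HVVR, PVVR) and diameter-stratified Dice
    scores, and reproduces the nonparametric statistical layer (Kruskal-Wallis,
    Bonferroni-corrected pairwise Mann-Whitney tests, percent-decrease summaries,
    Spearman correlation maps, and disease-stage subgroup analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
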