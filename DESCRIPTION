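Package: mseconn
Title: Multiscale Entropy and Functional Connectivity Analysis of
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes voxel-wise and region-wise multiscale sample entropy
    (SampEn/MSE) and seed-to-seed functional connectivity from preprocessed
    resting-state fMRI, and carries out the accompanying group statistics:
    rank-based inverse-normal (Rankit) covariate transforms, factorial
    Group-by-Sex ANCOVA with Type-III tests and partial eta squared,
    network-wise Benjamini-Hochberg false-discovery-rate control, partial
    correlations with symptom scores, and two-group comparison of partial
    correlations for complexity-connectivity linkages.  Includes a synthetic
    two-run ROI time-series cohort generator with known complexity and
    connectivity structure for end-to-end validation, plus framewise
    displacement quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    car,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
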