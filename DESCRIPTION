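Package: perturbrad
Title: Perturbation-Based Repeatability Analysis of Radiomics and Dosiomics Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Assesses the repeatability of radiomics (CT) and dosiomics (dose map)
    texture features under image perturbation. Volumes and region-of-interest masks
    are perturbed by random rigid transforms and contour randomization through
    smoothed random displacement fields; a 1302-feature vector (first-order and
    five gray-level texture-matrix classes across an original + Laplacian-of-Gaussian
    + wavelet filter bank) is extracted per perturbation; per-feature repeatability
    is quantified by the one-way random-effects intraclass correlation coefficient,
    binarized at 0.9, compared between modalities, and correlated with image
    characteristics (entropy, uniformity, variance). Synthetic phantom cohorts with
    controllable texture heterogeneity make the full pipeline testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
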