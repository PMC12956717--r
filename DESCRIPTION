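Package: ctquant
Title: Quantitative Thoracic CT Biomarkers on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic quantification of thoracic CT imaging biomarkers
    with a seeded synthetic thorax phantom carrying analytically known ground
    truth. Implements the four biomarker branches used in quantitative
    cardiopulmonary CT: lung densitometry (LAV%, Perc15, MLD), airway wall
    morphometry (FWHM ray casting, WA%, Pi10 regression), pulmonary vessel
    profiling (skeleton/distance-transform cross-sectional areas, BV5%,
    box-counting fractal dimension) and cardiac indices (Agatston coronary
    calcium score, left-ventricular mass, ejection fraction, stroke volume).
    Also provides the accompanying evaluation harness (Dice/IoU, soft Dice
    loss, stratified splits, augmentation) and trial-design statistics
    (two-sample-means sample size, GOLD grading, stratified randomization,
    Benjamini-Hochberg adjustment, correlation matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
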