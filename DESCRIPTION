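Package: morphorec
Title: Regression-Based Reconstruction of Missing 3D Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how accurately multiple linear regression
    can reconstruct missing landmark coordinates on damaged bones. Implements
    generalized Procrustes analysis, sliding of surface semilandmarks by
    thin-plate-spline bending energy, regression-based imputation of missing
    landmarks trained on an undamaged reference sample, and a leave-one-out
    damage-simulation study with Procrustes-distance accuracy metrics and
    t-test/ANOVA/Tukey comparisons. Includes a seeded synthetic-data generator
    for cranial (zygomatic-like) landmark configurations with low-rank spatial
    covariance, population mean offsets, and digitization noise, plus readers
    and writers for TPS and wide-CSV landmark files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
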