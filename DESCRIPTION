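Package: beready
Title: Endometrial Receptivity Dating from Targeted UMI Expression Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for transcriptomic dating of the endometrial window of
    implantation from targeted ligation-probe sequencing panels. Converts
    UMI-tagged reads into PCR-duplicate-corrected molecule counts, normalises
    expression by the geometric mean of housekeeper genes, and classifies
    samples into five ordered receptivity classes (pre-, early-, receptive,
    late-, post-receptive) with a PCA/Mahalanobis centroid model using Horn's
    parallel analysis for component retention and chi-square outlier gating.
    Includes repeated stratified cross-validation, concordance accounting,
    lower-tailed Fisher's exact proportion tests, per-gene differential
    expression and interaction ANOVA, and a synthetic-data generator that
    emulates phase-structured counts and UMI-tagged reads with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
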