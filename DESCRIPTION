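Package: ctshapes
Title: Trajectory-Shape Analysis of Cortical Thickness Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models age-related changes in regional cortical thickness as
    polynomial developmental trajectories and compares their shape (slope,
    curvature, aberrancy) between diagnostic groups. Provides multi-site
    harmonization by regression on acquisition center, goodness-of-fit
    masking with false discovery rate control, entropy-guided subject
    subsampling to manufacture within-group variability of shape
    coefficients, mean-centered and behavioral partial least squares with
    permutation tests and bootstrap ratios, a turning-point statistic for
    negative-curvature trajectories, and linear support vector machine
    classification of developmental trajectories under a split-then-subsample
    cross-validation scheme. Includes a synthetic cohort generator emulating
    multi-center structural MRI phenotype and thickness tables so the full
    pipeline is testable without any data download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
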