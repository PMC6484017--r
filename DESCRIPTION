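Package: chewmix
Title: Two-Coloured Chewing-Gum Mixing Test Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies masticatory performance from scanner images of
    flattened two-coloured chewing-gum wafers. Implements a fully automated
    colour-based bolus segmentation (mean-shift superpixels in CIE Lab,
    log-distance map to the estimated background colour, two-class k-means),
    the variance of the hue histogram (VhH) colour-mixing statistic, and the
    repeated-measures statistical battery used in clinical mixing-test
    studies: mixed ANOVA with Mauchly sphericity testing and
    Greenhouse-Geisser/Huynh-Feldt corrections, Bonferroni and Games-Howell
    post hoc comparisons, Welch heteroscedastic ANOVA, normality and
    homogeneity gatekeeping, and Gaussian generalized estimating equations
    with robust standard errors. Ships seeded generators for synthetic wafer
    images with ground-truth masks and for synthetic longitudinal cohorts,
    enabling end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    png,
    nortest,
    car,
    sandwich,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
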