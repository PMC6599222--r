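Package: choroidAgree
Title: Agreement-Based Validation of Choroidal Thickness Change Detection
    Without Ground Truth
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for validating automated detection of
    choroidal thickness changes on OCT B-scans when no ground truth exists.
    Implements rater repeatability (intra-rater coefficient), the Williams'
    agreement index over four contour/displacement similarity measures
    (Dice, Jaccard, bidirectional local distance, diffZ), and a
    leave-one-out artificial-ground-truth power analysis (paired t-test,
    Cohen's d with pooled standard deviation). Includes a synthetic cohort
    generator that emulates OCT raster geometry, smooth choroid-sclera
    interface contours, interval- and region-dependent longitudinal growth,
    noisy expert raters with triple repeats, and the balanced
    expert-to-scan allocation design, so the whole framework can be
    exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
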