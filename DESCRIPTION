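Package: fedcox
Title: Federated Cox Proportional-Hazards Regression via Survival Stacking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Cox proportional-hazards models on horizontally
    partitioned right-censored survival data without sharing subject-level
    rows. Each party survival-stacks its data into a classification dataset
    (exactly per failure time or on a shared time-bin grid) and the parties
    run federated logistic regression with size-weighted gradient
    aggregation; the covariate-block coefficients approximate the Cox
    partial-likelihood estimates. Includes a distributed protocol for
    Schoenfeld residual diagnostics, a centralized Cox partial-likelihood
    reference fit, Wald inference, a proportional-hazards simulator, and
    experiment harnesses for optimizer, bin-count and federated-versus-
    individual comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
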