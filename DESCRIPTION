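Package: uroscent
Title: Integrative Urine-Based Prostate Cancer Biosensing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of urine-based prostate cancer
    detection combining four data streams: scoring of double-blind canine
    scent-detection carousel trials with binomial chance statistics;
    GC-MS volatilome statistics (prevalence filtering, Wilcoxon screening,
    sure-independence screening with SCAD-penalized logistic regression,
    Firth bias-reduced final fits, and jackknife leave-one-out ROC);
    urinary 16S microbiota processing (three-phase reagent-contaminant
    removal with negative extraction controls, rarefaction, Bray-Curtis and
    unweighted UniFrac beta diversity, principal coordinates analysis, and
    Mann-Whitney differential abundance); and a multilayer-perceptron
    emulator of canine diagnoses trained on total-ion chromatograms, with
    network skeletonization for dominant-peak extraction and
    auto-associative reconstruction filtering for per-sample anomaly
    detection. A synthetic-data generator reproduces the statistical
    structure each arm assumes, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    pROC,
    vegan,
    ape,
    picante,
    phangorn,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
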