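Package: amyscreen
Title: Blood-Biomarker Screening for Amyloid PET Positivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation of plasma biomarkers (immunoassay and mass-spectrometry
    amyloid-beta measures, phospho-tau181) as pre-screening tests for cortical
    amyloid PET positivity in dementia-free older adults. Provides a seeded
    synthetic cohort generator matched to published summary statistics, a
    two-component Gaussian mixture model for deriving the PET SUVR positivity
    cut-point, logistic concordance models with ROC/AUC analysis, paired DeLong
    AUC comparisons and Youden cut-point selection, and screening-programme
    economics: number needed to screen, number proceeding to scan, predictive
    values, scans saved and relative cost across prevalence and cost-ratio
    ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
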