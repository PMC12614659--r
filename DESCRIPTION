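Package: crcqmp
Title: Rule-Based Quality Management for Colorectal Cancer EMR Staging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule-based quality management process (QMP) for oncology
    electronic-medical-record data. Extracts TNM (tumor, node, metastasis)
    and SEER summary-stage codes from free-text pathology and imaging
    reports with a phrase lexicon grounded in the Korean clinical guideline
    for colorectal cancer and SEER Summary Stage 2018, imputes missing
    staging variables in a patient-level cohort table with a full evidence
    change log, and quantifies the data-quality improvement (missing rates,
    audit error rates, concordance, and gradient-boosting model performance
    and feature importance) before versus after quality management. Ships a
    synthetic cohort and report generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
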