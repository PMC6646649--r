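Package: cadreader
Title: Multi-Reader Multi-Case Analysis of AI-CAD-Assisted Mammography Recall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for sequential-design reader studies in screening
    mammography, in which radiologists first read each case unaided and then
    re-read it with artificial-intelligence computer-aided-detection (AI-CAD)
    marks visible. Provides validated tabular schemas for cases, reader recall
    decisions, and CAD marks; cohort accounting for retrospective
    (prior-mammogram) case selection; per-reader cancer detection rate and
    false-positive recall metrics with localization-aware scoring; pooled
    readers-as-a-group ROC curves built from aggregate recall scores with
    trapezoidal AUC; a counterfactual "theoretical reader" transform; case- and
    reader-axis bootstrap confidence intervals for the percentage change in
    pooled AUC; and a calibrated synthetic study generator so that the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
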