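Package: nephropep
Title: Urinary Peptide Biomarker Discovery for Kidney Function Decline
    Under RAS Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for labeling diabetic patients under renin-angiotensin
    system inhibitor treatment as having controlled or uncontrolled kidney
    function from longitudinal estimated glomerular filtration rate (eGFR)
    trajectories, and for discovering urinary peptide biomarkers of
    non-response. Implements the CKD-EPI 2009/2012 and EKFC cystatin C
    estimating equations with analytic inversion, per-patient percentage-slope
    labeling rules, internal-standard normalization and detection-frequency
    filtering of peptide intensity matrices, Wilcoxon/Spearman differential
    screening per eGFR equation, cross-equation concordance panel selection,
    an RBF support vector machine panel classifier with take-one-out
    backward refinement scored by leave-one-out AUC, DeLong ROC inference,
    label-concordance analysis, and a seeded synthetic-cohort generator with
    known ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    e1071,
    jsonlite,
    generics,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
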