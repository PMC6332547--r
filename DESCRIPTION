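Package: pneumodose
Title: Normal-Lung Definitions, Dose-Volume Metrics, and Radiation
    Pneumonitis Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the choice of normal-lung definition
    (Total Lung, Lung-PGTV, Lung-PTV) changes dose-volume histogram
    metrics (V5, V20, mean lung dose) and the prediction of grade >= 2
    radiation pneumonitis after thoracic intensity-modulated
    radiotherapy. Provides voxel-mask geometry with Euclidean margin
    expansion, DVH metric extraction, a synthetic thorax phantom and
    cohort simulator, the univariate statistical battery used in
    retrospective pneumonitis studies (2x2 odds ratios with Wald
    inference, univariate logistic regression, Mann-Whitney U, paired
    mean differences, repeated-measures ANOVA), ROC/AUC comparison with
    DeLong's paired test, and Lyman (probit) NTCP model fitting with
    iso-risk cutoff-dose inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
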