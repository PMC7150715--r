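Package: ogttpcs
Title: Principal Component Scores of Glucose Homeostasis from the Oral
    Glucose Tolerance Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes fasting and dynamic indices of insulin sensitivity,
    insulin secretion and beta-cell function from 2-hour oral glucose
    tolerance test (OGTT) data (HOMA-IR, QUICKI, Matsuda, OGIS, Stumvoll
    MCR/ISI/PH1/PH2, insulinogenic indices, ISSI-2, C-peptide derived
    insulin secretion), projects principal-component derived glucose
    homeostasis scores (PCS1-3) from a 17-variable loading matrix, and
    provides the surrounding cohort analysis: chained-equation imputation,
    Spearman correlation maps, Welch and contingency tests, univariable
    logistic regression with profile-likelihood intervals, random-forest
    permutation importance, and linear mixed models for visit effects.
    A calibrated synthetic-cohort generator emulates longitudinal OGTT
    studies in pregnancy so the whole pipeline is testable without
    confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    lme4,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
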