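Package: adcb
Title: Breast Apparent Diffusion Coefficient (ADC-B) Categorization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Derives apparent diffusion coefficient (ADC) category thresholds
    for contrast-enhancing breast lesions from cumulative malignancy-rate
    curves and ROC/PPV analysis, and classifies lesions into the six ADC-B
    categories (B0 non-diagnostic, B1 no enhancing lesion, B2-B5 decreasing
    ADC / increasing malignancy rate). Includes the supporting validation
    statistics (Student/Welch t tests, one-way ANOVA, Games-Howell post hoc
    comparisons, multivariable linear regression with adjusted R-squared), a
    calibrated synthetic lesion-cohort generator for end-to-end testing of
    the derivation, and a pipeline runner that writes curve, ROC, scheme and
    per-category audit tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
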