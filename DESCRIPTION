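Package: hragree
Title: Accuracy and Agreement Analysis for Paired Heart-Rate Monitors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Validation toolkit for wrist-worn photoplethysmography heart-rate
    monitors against a reference electrocardiogram in repeated-measures stress
    protocols. Implements mixed-effects limits of agreement, the variance-
    components concordance correlation coefficient, coverage probability, the
    total deviation index, the coefficient of individual agreement and the
    repeatability coefficient, together with MAE/MAPE accuracy indices against
    a clinically acceptable difference, a mixed-effects phase ANOVA with
    Satterthwaite degrees of freedom and Tukey contrasts, a seeded
    subject-level cluster bootstrap with BCa intervals, and a synthetic
    Trier Social Stress Test study generator with a configurable wearable
    error model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
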