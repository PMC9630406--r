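Package: t1dstage
Title: Metabolic Staging, Progression Likelihood Scoring and Screening
    Economics for Presymptomatic Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing childhood public-health screening cohorts
    for presymptomatic type 1 diabetes. Implements rule-based metabolic
    staging of multiple-islet-autoantibody-positive children (2015
    consensus and revised ADA criteria), a composite progression
    likelihood score (Cox proportional-hazards and logistic-regression
    forms) with centile-based stage 1a/1b substaging, Kaplan-Meier
    estimation of progression risk with annualised-risk conversion,
    refitting of the score-building procedure (univariable and backward
    multivariable Cox selection, penalised logistic regression with
    random-forest importance), score evaluation (decile risk and
    sensitivity curves, threshold diagnostics, bootstrap intervals), and a
    screening, recruitment and cost model for prevention trials. A
    synthetic-cohort generator reproduces the statistical structure these
    analyses assume so that the whole pipeline is testable without
    individual-level clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    ranger,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
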