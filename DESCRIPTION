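Package: aceselect
Title: Model Selection for Cumulative and Multiple Individual Risk
    Characterizations of Adverse Childhood Experiences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for operationalizing self-reported Adverse Childhood
    Experience (ACE) survey items as predictors of binary adult health
    outcomes, and for statistically choosing among competing predictor
    characterizations. Implements screening and imputation rules for
    survey responses, exposure coding at configurable frequency
    thresholds, cumulative-risk (continuous and categorical ACE score)
    and multiple-individual-risk (MIR) logistic model designs,
    maximum-likelihood logistic fits that retain per-observation
    log-likelihood, score and Hessian contributions, descriptive fit
    metrics (AIC, Nagelkerke pseudo R-squared, concordance statistic,
    variance inflation factors), the two-step Vuong procedure for
    partially non-nested model comparison (variance/distinguishability
    test with a weighted chi-square null, followed by the closeness
    z-test) with an AIC fallback rule, a full selection workflow
    producing best-fit, comparison-matrix and odds-ratio reports, and a
    seeded Gaussian-copula generator of synthetic survey data for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
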