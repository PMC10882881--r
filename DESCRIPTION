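Package: predcal
Title: Calibration and Clinical Evidence Assessment for Variant Effect Predictors
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Assessment toolkit for computational variant-effect and risk
    predictors. Computes the standard continuous-target metrics (R-squared,
    RMSE, Pearson, Spearman, tie-corrected Kendall tau-b) and binary metrics
    (tie-aware ROC/AUC, truncated AUC over the low false-positive-rate
    region, MCC, likelihood ratios, diagnostic odds ratio), estimates the
    local positive likelihood ratio of pathogenicity from labeled scores by
    adaptive score windowing, derives ACMG/AMP evidence-strength score
    thresholds under an exponential evidence-combination model, transfers
    prior-dependent quantities (PPV, posterior probability of pathogenicity,
    relative risk) to a stated target class prior, and attaches bootstrap
    confidence intervals and permutation p-values throughout. Includes
    synthetic score generators with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
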