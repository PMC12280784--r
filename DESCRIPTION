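Package: prevcea
Title: Cost-Effectiveness Analysis of Multidomain Dementia-Prevention Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-based cost-effectiveness analysis for four-arm prevention
    trials in older adults, modelled on multidomain lifestyle plus omega-3
    supplementation trials against cognitive decline. Provides a synthetic
    trial generator with known ground truth (baseline covariates, composite
    cognitive Z-score trajectories under a mixed model, gamma-distributed
    healthcare resource use, missing-at-random economic data),
    payer-perspective costing from a configurable tariff table (fixed tariffs,
    per-diem rates, defined-daily-dose drug pricing, gamma-sampled
    components), descriptive tables with bias-corrected and accelerated (BCa)
    bootstrap confidence intervals and Kruskal-Wallis tests,
    predictive-mean-matching multiple imputation of cumulative costs with
    Rubin pooling and a Hausman-type attrition check, covariate adjustment via
    gamma/log-link GLM for costs and a linear mixed model for the composite
    Z-score, and a bootstrap cost-effectiveness core: ICERs with
    cost-effectiveness-plane quadrants, 95 percent confidence ellipses, and
    cost-effectiveness acceptability curves over a willingness-to-pay grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    lme4,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
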