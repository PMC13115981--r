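Package: afcea
Title: Cost-Effectiveness Modelling of Upstream Thromboembolic Risk Detection in Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Six-state annual-cycle cohort Markov model evaluating an
    AI-guided strategy for upstream thromboembolic risk detection against
    usual care in adults aged 65 and over at high risk of atrial
    fibrillation. Provides synthetic-cohort generation from published
    marginal statistics, incidence-rate handling and rate-to-probability
    conversion, calibration of transition intensities to lifetime event
    targets, sex-stratified clinical outcomes, payer and societal
    cost-effectiveness (QALYs, ICER, net monetary benefit), probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    one-way deterministic sensitivity analysis, population-impact
    stratification and short-horizon budget impact.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
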