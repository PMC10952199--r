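Package: covselsim
Title: Full-Model Versus Backward-Elimination Confounder Selection in
    Simulated Observational Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for comparing causal effect estimation with a
    full prespecified confounder model against backward elimination of weak
    confounders, for binary outcomes. Implements Firth's bias-reduced logistic
    regression with intercept correction (FLIC), profile penalized likelihood
    confidence intervals and penalized likelihood-ratio tests; backward
    elimination at a configurable significance threshold; conditional odds
    ratio and standardized (g-computation) marginal risk ratio, odds ratio and
    risk difference estimators; selected-model and global bootstrap percentile
    intervals with selection-stability diagnostics (relative conditional bias
    and root mean squared difference ratio); data-generating mechanisms for
    confounded binary-outcome scenarios with calibrated intercepts and
    large-sample true estimands; a Monte-Carlo engine computing bias, variance,
    MSE and relative efficiency per scenario; and closed-form ordinary least
    squares bias-variance trade-off calculations including the crossover
    sample size at which omitting a covariate stops paying off.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
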