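#!/usr/bin/env Rscript
# Closed-form OLS bias-variance trade-off: tabulate MSE under the
# include-vs-omit strategies across sample sizes and report the crossover
# sample size for a moderately confounded setting (chosen so the crossover
# lands near n = 60, the qualitative regime of interest for small studies).
#
# Usage: Rscript analysis/05_theory.R

library(covselsim)
dir.create("results", showWarnings = FALSE)

pars <- list(beta_LY = 0.15, var_A = 1, var_L = 1, rho_AL = 0.55, sigma2 = 1)
curve <- do.call(ols_tradeoff_curve, c(pars, list(n_grid = 3:200)))
utils::write.csv(curve, "results/theory_tradeoff_curve.csv", row.names = FALSE)

n_star <- do.call(crossover_n, pars)
message(sprintf(
  "Crossover at n* = %.1f: omitting the covariate lowers the MSE for n < %.0f",
  n_star, n_star))
message("MSE curves: results/theory_tradeoff_curve.csv")
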