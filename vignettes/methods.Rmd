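---
title: "Full-model versus backward-elimination confounder adjustment: models, design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-model versus backward-elimination confounder adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covselsim)
```

## The scientific question

When estimating the causal effect of a binary exposure $A$ on a binary
outcome $Y$ from observational data, analysts start from a prespecified set
of potential confounders $L$ chosen on background knowledge. Should the
outcome model keep all of them ("full model"), or may backward elimination of
the statistically weak ones buy precision at an acceptable price in bias?
This package implements the machinery to answer that question by simulation:
a data-generating module for confounded binary-outcome scenarios, a
penalized-likelihood estimation stack, backward elimination, g-computation
estimators for marginal effects, bootstrap-based post-selection inference,
a Monte-Carlo performance engine, and the closed-form linear-model analysis
of the underlying bias–variance trade-off.

## The bias–variance trade-off in closed form

For the linear model $Y = \theta A + \beta_{LY} L + \varepsilon$ with
$\mathrm{Cor}(A, L) = \rho$, omitting $L$ biases the OLS exposure coefficient
by $\beta_{LY}\,\mathrm{Cov}(A,L)/\mathrm{Var}(A)$ but removes the variance
inflation $1/(1-\rho^2)$ of the adjusted estimator. Omission lowers the MSE
exactly when

$$\mathrm{Bias}_{omit}^2 < \mathrm{Var}_{full} - \mathrm{Var}_{omit},$$

and because both variances scale as $1/n$ while the bias does not, there is a
crossover sample size $n^\*$ below which omission wins. `ols_mse_components()`
returns the three terms and `crossover_n()` returns
$n^\* = (\mathrm{Var}_{full}(1) - \mathrm{Var}_{omit}(1))/\mathrm{Bias}_{omit}^2$.

```{r}
crossover_n(beta_LY = 0.15, var_A = 1, var_L = 1, rho_AL = 0.55, sigma2 = 1)
```

With a covariate that is strongly linked to the exposure and weakly to the
outcome, the crossover lands near $n = 60$: in smaller samples the variance
argument dominates. The same inequality is evaluated empirically, per
scenario, by the simulation engine (`inequality_check()`).

## Estimation stack

**Firth's penalized likelihood.** All logistic models are fitted by
maximizing $\log L(\beta) + \tfrac12 \log |I(\beta)|$ with the modified score
$U^*_j = \sum_i \{y_i - \pi_i + h_i(\tfrac12 - \pi_i)\} x_{ij}$, where $h_i$
are weighted hat-matrix diagonals. This removes the $O(1/n)$ bias of maximum
likelihood and keeps estimates finite under separation — essential here,
because the rare-event scenarios (3% events, up to 26 parameters) separate
regularly. Newton scoring uses step-halving (at most 5 halvings per step)
until the penalized likelihood is non-decreasing, and stops when the largest
absolute modified score falls below $10^{-6}$ (at most 50 iterations); these
values follow common practice in penalized-likelihood software. Inside the
backward-elimination drop tests, where only the constrained likelihood
*value* is needed, iteration additionally stops once a full Newton step
improves the penalized likelihood by less than $10^{-7}$ — near a quadratic
optimum the remaining gap is then of the same order, far below what could
move a p-value across the 0.157 threshold.

**FLIC.** The Firth penalty shifts predicted probabilities toward 1/2, which
distorts standardized risks in rare-event settings. FLIC keeps the Firth
slopes and re-estimates the intercept by plain maximum likelihood with the
rest of the linear predictor as an offset, which forces the mean predicted
risk to equal the observed event fraction. All effect estimates are taken
from FLIC fits: the conditional log odds ratio is the exposure coefficient
(identical in Firth and FLIC fits), and the marginal effects are computed by
g-computation — predict each subject's risk with exposure set to 1 and to 0,
average, and contrast the two standardized risks as a ratio (mRR), an odds
ratio (mOR) and a difference (mRD).

**Inference.** Profile penalized likelihood intervals invert the penalized
likelihood-ratio statistic with one coefficient fixed (root-finding outward
from the estimate in Wald-SE steps); Wald intervals use the inverse penalized
information. The penalized likelihood-ratio test refits the full design with
the tested coefficients constrained to zero, so that both likelihoods carry
the same information penalty. Comparing separately-fitted designs instead
would add the difference of two information determinants to the statistic —
a systematic, dimension-dependent term that in an early version of this
package inflated every drop "significance" enough to retain all 24
candidates; the constrained-refit construction is therefore load-bearing.

**Backward elimination.** Classical one-at-a-time elimination: refit, compute
each remaining candidate's drop p-value (penalized LR by default, Wald as an
option, since published selection studies rarely state which they used), remove
the largest p-value if it exceeds $\alpha = 0.157$ (the AIC-equivalent
threshold), ties broken by lowest column index, no re-entry. Exposure and
intercept are never candidates.

## Data-generating mechanisms

Two experiments, both with binary exposure and outcome generated from
logistic models:

* **Experiment 1** (proof of concept, 144 scenarios): one standard-normal
  covariate; null conditional exposure effect; covariate–exposure and
  covariate–outcome log odds ratios on the grid $\{0, 0.1, \ldots, 0.5\}$
  (six equally spaced values — the only uniform grid compatible with 144
  scenarios given $2 \times 2$ design cells); $n \in \{60, 120\}$; event
  fraction $\in \{0.5, 0.2\}$.
* **Experiment 2** (realistic, 3960 scenarios): 24 standard-normal covariates
  with constant pairwise correlation 0.3 (drawn exactly via a shared normal
  factor); 12 fixed weak confounders at $(\log 1.05, \log 1.05)$; four
  exchangeable sets of three covariates, each set assigned one
  $(\beta_{LA}, \beta_{LY})$ pair from $\{0, \log 1.05, \log 1.2\}^2$ — sets
  are canonicalized by sorting, so the $\binom{9+4-1}{4} = 495$ multisets
  enumerate without duplicates; conditional exposure effect
  $\in \{0, \log 1.5\}$; expected events $\in \{50, 200\}$ and event fraction
  $\in \{0.2, 0.03\}$, giving $n \in \{250, 1000, 1667, 6667\}$.

**Intercept calibration.** The exposure-model intercept is calibrated so that
the expected exposure prevalence is 0.5 — the balanced default, chosen
because no prevalence is otherwise implied — and the outcome-model intercept
so that the marginal event fraction (over covariates and the exposure they
induce) matches the scenario. Both are monotone one-dimensional problems,
solved by bisection-safeguarded Newton on a fixed-seed Monte-Carlo sample of
$10^6$ draws to tolerance $10^{-4}$ on the probability scale. Only the joint
distribution of the two linear predictors $(\beta_{LA}'L, \beta_{LY}'L)$
matters, and under the multivariate-normal covariate model that pair is
bivariate normal, so calibration samples in two dimensions rather than 24;
the marginal event fraction is integrated analytically over the Bernoulli
exposure given the covariates.

**Truth.** The true conditional log OR is $\theta$ by construction. Marginal
truths come from a large-sample approximation at $N = 10^6$: average the two
potential-outcome risks over draws of $\beta_{LY}'L$ and contrast. A null
$\theta$ gives exactly null marginal effects (the potential-outcome risks
coincide row-wise), so no approximation error enters the null scenarios.

**Seeds.** Every replicate's seed derives deterministically from (root seed,
scenario id, replicate index) via multiplicative hashing below $2^{31}$,
so results are reproducible and independent of scheduling, and dataset
generation never disturbs the caller's RNG state.

**What the generator does not emulate.** All covariates are continuous,
jointly normal, with a single exchangeable correlation; there are no
mediators, colliders, unmeasured confounders, nonlinearities or
interactions, and the fitted outcome model is correctly specified up to
variable inclusion. Passing tests therefore demonstrate the selection
trade-off under a correctly specified working set — not robustness to
model misspecification or to data with skewed or categorical covariates.

## Monte-Carlo engine and performance measures

Per scenario and strategy (full / backward elimination / unadjusted), the
engine records the four effect estimates per replicate and reports bias,
variance and MSE against the scenario truths, the relative efficiency
MSE(BE)/MSE(full), the mean number of eliminated true confounders, and
non-convergence counts (non-convergent replicates are dropped, not imputed;
FLIC makes them rare). Variance uses the $1/m$ convention so that
$\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{variance}$ holds exactly — all
three moments are computed from the same replicate vector. Coverage
bookkeeping (Wald and profile-penalized-likelihood intervals for the
conditional log OR, percentile bootstrap for the marginal log RR at a
reduced 200 resamples) is available behind the `coverage` flag; both
interval types are provided so either convention can be examined.

**Bootstrap inference and stability.** `bootstrap_ci()` implements the
percentile bootstrap (B = 500 by default) in three modes: refit the full
model per resample; refit the once-selected model per resample (the
"invalid" selected-model interval); or rerun the entire elimination inside
every resample (global bootstrap). `stability_measures()` reports the
relative conditional bias, $100(\bar t_b - t_{full})/t_{full}$, and the root
mean squared difference ratio,
$\sqrt{\smash[b]{\overline{(t_b - t_{full})^2}}}/SE_{full}$, with globally
re-selected resample estimates $t_b$. The literature introducing these
measures leaves denominator choices open (full-model estimate versus median;
model-based versus bootstrap standard error); the construction here uses the
model-based Wald SE for the conditional log OR and the bootstrap SD of
full-model resamples for marginal estimands, both exposed as switches
rather than asserted to be the only defensible reading.

## Problem sizes used in the tests and scripts

The full-scale design calls for 10,000 replicates per Experiment-1 scenario
and 1000 per Experiment-2 scenario. The package's own checks run, as its
chosen desk-scale study conditions:

* Experiment 1: all 144 scenarios at 500 replicates (the acceptance script
  recomputes the inequality proportions at this size). At 500 replicates the
  indicator of the inequality is noticeably noisy for boundary scenarios,
  and the plug-in $\widehat{\mathrm{bias}}^2$ carries an upward
  $\mathrm{Var}/m$ inflation, which together depress the conditional-OR
  proportion by roughly 3 percentage points relative to a 2500-replicate
  run of the same code.
* Experiment 2: property-based checks on stratified scenario samples
  (parameter recovery on 20 scenarios at 200 replicates; relative
  efficiency on 40 scenarios at 12 replicates, summarized as a geometric
  mean because per-scenario MSE ratios at 12 replicates are individually
  noisy). The full-grid run at 50–100 replicates per scenario is provided
  as `analysis/03_experiment2.R` and is an overnight single-CPU job with
  per-scenario checkpointing.

## Known limitations

* No clinical patient-level data ship with the package; the post-selection
  bootstrap interval comparison is demonstrated on a synthetic analysis
  dataset instead (`analysis/06_bootstrap_stability.R`).
* Exposure prevalence is a calibration target with default 0.5; the original
  study does not state one.
* The RCB/RMSDR formulas are an operationalization, as flagged above.
* Backward elimination is the only selection procedure implemented; forward
  or stepwise selection, augmented backward elimination, and
  penalization-based selectors are out of scope.
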