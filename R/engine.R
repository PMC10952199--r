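effect_names <- c("log_cOR", "log_mRR", "log_mOR", "mRD")

#' Monte-Carlo evaluation of one scenario
#'
#' Generates `n_reps` replicate datasets (replicate seeds derived
#' deterministically from `root_seed` and the scenario id, so results do not
#' depend on execution order), applies each estimation strategy, and computes
#' Monte-Carlo bias, variance and MSE of each effect estimate against the
#' scenario's true values (true conditional log OR is `theta`; marginal
#' truths come from [true_marginal_effects()]). Bias, variance and MSE are
#' computed from the same replicate vector with the 1/m variance convention,
#' so `mse = bias^2 + variance` holds exactly. Non-convergent replicates are
#' excluded per strategy and counted.
#'
#' @param scenario one calibrated scenario row.
#' @param n_reps number of Monte-Carlo replicates (>= 2).
#' @param strategies subset of `c("full", "backward", "unadjusted")`.
#' @param root_seed root seed for the replicate streams.
#' @param alpha backward-elimination threshold.
#' @param truth optional precomputed [true_marginal_effects()] result.
#' @param coverage if `TRUE`, also record per-replicate interval coverage:
#'   Wald and profile-penalized-likelihood intervals for the conditional log
#'   OR and a percentile bootstrap for the marginal log RR.
#' @param boot_B bootstrap resamples per replicate for log mRR coverage.
#' @param level nominal coverage level.
#' @return an object of class `scenario_performance`: list with `performance`
#'   (long data.frame: strategy, estimand, bias, variance, mse,
#'   n_effective), `relative_efficiency` (named per estimand,
#'   MSE backward / MSE full when both strategies were run),
#'   `n_nonconverged` per strategy, `mean_eliminated_confounders`,
#'   `coverage` (data.frame or NULL), `truth` and `scenario_id`.
#' @export
run_scenario <- function(scenario, n_reps,
                         strategies = c("full", "backward", "unadjusted"),
                         root_seed = 1L, alpha = 0.157, truth = NULL,
                         coverage = FALSE, boot_B = 200L, level = 0.95) {
  stopifnot(n_reps >= 2)
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (is.null(truth)) truth <- true_marginal_effects(scenario)
  true_vals <- c(log_cOR = scenario$theta, log_mRR = truth$log_mRR,
                 log_mOR = truth$log_mOR, mRD = truth$mRD)

  b <- scenario_betas(scenario)
  conf_cols <- which(covariate_role(b$beta_LA, b$beta_LY) == "confounder") + 2L

  est <- array(NA_real_, dim = c(n_reps, length(strategies), 4L),
               dimnames = list(NULL, strategies, effect_names))
  elim_conf <- rep(NA_real_, n_reps)
  cov_rows <- list()

  for (r in seq_len(n_reps)) {
    ds <- generate_dataset(scenario, derive_seed(root_seed, scenario$scenario_id, r))
    for (s in strategies) {
      res <- tryCatch(estimate_effects(ds, s, alpha = alpha),
                      error = function(e) NULL)
      if (is.null(res) || !res$converged) next
      est[r, s, ] <- unlist(res[effect_names], use.names = FALSE)
      if (s == "backward")
        elim_conf[r] <- length(setdiff(conf_cols, res$retained))
      if (coverage) {
        cov_rows[[length(cov_rows) + 1L]] <-
          replicate_coverage(ds, res, s, true_vals, boot_B, level,
                             derive_seed(root_seed, scenario$scenario_id, r + n_reps))
      }
    }
  }

  perf <- do.call(rbind, lapply(strategies, function(s) {
    do.call(rbind, lapply(effect_names, function(e) {
      x <- est[, s, e]
      x <- x[is.finite(x)]
      m <- length(x)
      bias <- mean(x) - true_vals[[e]]
      variance <- mean((x - mean(x))^2)
      data.frame(scenario_id = scenario$scenario_id, strategy = s, estimand = e,
                 bias = bias, variance = variance,
                 mse = bias^2 + variance, n_effective = m)
    }))
  }))
  rownames(perf) <- NULL

  rel_eff <- NULL
  if (all(c("full", "backward") %in% strategies)) {
    rel_eff <- vapply(effect_names, function(e) {
      perf$mse[perf$strategy == "backward" & perf$estimand == e] /
        perf$mse[perf$strategy == "full" & perf$estimand == e]
    }, numeric(1))
  }

  n_nonconv <- vapply(strategies, function(s) sum(!is.finite(est[, s, 1L])),
                      integer(1))
  if (any(n_nonconv >= n_reps))
    stop("all replicates non-convergent for strategy: ",
         paste(strategies[n_nonconv >= n_reps], collapse = ", "))

  structure(list(
    performance = perf,
    relative_efficiency = rel_eff,
    n_nonconverged = n_nonconv,
    mean_eliminated_confounders =
      if ("backward" %in% strategies) mean(elim_conf, na.rm = TRUE) else NA_real_,
    coverage = if (coverage) summarize_coverage(do.call(rbind, cov_rows)) else NULL,
    truth = truth,
    scenario_id = scenario$scenario_id,
    n_reps = n_reps
  ), class = "scenario_performance")
}

replicate_coverage <- function(ds, res, strategy, true_vals, boot_B, level, seed) {
  fit <- res$fit
  j <- match("A", colnames(fit$X))
  wald <- wald_ci(fit, j, level)
  ppl <- tryCatch(
    profile_penalized_likelihood_ci(fit$X, ds$Y, j, level = level),
    error = function(e) c(NA_real_, NA_real_))
  boot <- tryCatch({
    mode <- switch(strategy, full = "full", unadjusted = "full",
                   backward = "boot_selected")
    ci <- bootstrap_ci(ds, "log_mRR", mode = mode, B = boot_B, level = level,
                       seed = seed)
    c(ci$lower, ci$upper)
  }, error = function(e) c(NA_real_, NA_real_))
  data.frame(
    strategy = strategy,
    wald_cOR = wald[1] <= true_vals[["log_cOR"]] & true_vals[["log_cOR"]] <= wald[2],
    ppl_cOR = ppl[1] <= true_vals[["log_cOR"]] & true_vals[["log_cOR"]] <= ppl[2],
    boot_mRR = boot[1] <= true_vals[["log_mRR"]] & true_vals[["log_mRR"]] <= boot[2]
  )
}

summarize_coverage <- function(rows) {
  if (is.null(rows) || !nrow(rows)) return(NULL)
  agg <- stats::aggregate(rows[, -1L], by = list(strategy = rows$strategy),
                          FUN = function(x) mean(x, na.rm = TRUE))
  agg
}

#' Check the bias-variance inequality on a scenario's Monte-Carlo results
#'
#' TRUE when the squared bias of the omit strategy is smaller than the
#' variance reduction it buys, i.e. `bias_omit^2 < var_full - var_omit`, in
#' which case omitting the covariate(s) lowers the MSE of the effect
#' estimator.
#'
#' @param perf a `scenario_performance`.
#' @param estimand which effect estimate to check.
#' @param full,omit names of the two strategies being contrasted (in the
#'   single-covariate experiment the omit strategy is the unadjusted model).
#' @return logical.
#' @export
inequality_check <- function(perf, estimand = "log_cOR",
                             full = "full", omit = "unadjusted") {
  p <- perf$performance
  pick <- function(s, col) p[[col]][p$strategy == s & p$estimand == estimand]
  pick(omit, "bias")^2 < pick(full, "variance") - pick(omit, "variance")
}

#' Run the single-covariate experiment over a scenario grid
#'
#' For every scenario, runs the Monte-Carlo comparison of the
#' "always include the covariate" (full) versus "always omit" (unadjusted)
#' strategies and records the bias-variance inequality outcome for the
#' conditional log OR and the marginal log RR.
#'
#' @param scenarios calibrated Experiment 1 grid (defaults to the full
#'   144-scenario grid, calibrated on the fly).
#' @param n_reps Monte-Carlo replicates per scenario.
#' @param root_seed root seed.
#' @param progress print a progress line every 24 scenarios.
#' @return data.frame with one row per scenario: design columns, bias and
#'   variance of each strategy for both estimands, and logicals `ineq_cOR`,
#'   `ineq_mRR`.
#' @export
run_experiment1 <- function(scenarios = NULL, n_reps = 500L, root_seed = 1L,
                            progress = FALSE) {
  if (is.null(scenarios)) scenarios <- calibrate_scenarios(enumerate_scenarios_exp1())
  rows <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    perf <- run_scenario(sc, n_reps, strategies = c("full", "unadjusted"),
                         root_seed = root_seed)
    p <- perf$performance
    pick <- function(s, e, col) p[[col]][p$strategy == s & p$estimand == e]
    rows[[i]] <- data.frame(
      scenario_id = sc$scenario_id, bLA = sc$bLA1, bLY = sc$bLY1,
      n = sc$n, event_fraction = sc$event_fraction,
      bias_full_cOR = pick("full", "log_cOR", "bias"),
      bias_omit_cOR = pick("unadjusted", "log_cOR", "bias"),
      var_full_cOR = pick("full", "log_cOR", "variance"),
      var_omit_cOR = pick("unadjusted", "log_cOR", "variance"),
      bias_full_mRR = pick("full", "log_mRR", "bias"),
      bias_omit_mRR = pick("unadjusted", "log_mRR", "bias"),
      var_full_mRR = pick("full", "log_mRR", "variance"),
      var_omit_mRR = pick("unadjusted", "log_mRR", "variance"),
      ineq_cOR = inequality_check(perf, "log_cOR"),
      ineq_mRR = inequality_check(perf, "log_mRR")
    )
    if (progress && i %% 24L == 0L)
      message(sprintf("experiment 1: %d / %d scenarios done", i, nrow(scenarios)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportion of scenarios satisfying the bias-variance inequality
#'
#' @param exp1_results output of [run_experiment1()].
#' @return named vector of percentages for the conditional log OR and the
#'   marginal log RR.
#' @export
inequality_proportions <- function(exp1_results) {
  c(log_cOR = 100 * mean(exp1_results$ineq_cOR),
    log_mRR = 100 * mean(exp1_results$ineq_mRR))
}

#' Flatten a scenario's performance into one summary row
#'
#' @param scenario the scenario row.
#' @param perf the matching `scenario_performance`.
#' @return single-row data.frame with design columns, biases, relative
#'   efficiencies and DGM-composition flags, the unit of aggregation of the
#'   multi-covariate experiment's summary tables.
#' @export
scenario_results_row <- function(scenario, perf) {
  p <- perf$performance
  pick <- function(s, e, col) {
    v <- p[[col]][p$strategy == s & p$estimand == e]
    if (length(v)) v else NA_real_
  }
  comp <- scenario_composition(scenario)
  data.frame(
    scenario_id = scenario$scenario_id, theta = scenario$theta,
    event_fraction = scenario$event_fraction,
    expected_events = scenario$expected_events, n = scenario$n,
    bias_full_cOR = pick("full", "log_cOR", "bias"),
    bias_be_cOR = pick("backward", "log_cOR", "bias"),
    bias_unadj_cOR = pick("unadjusted", "log_cOR", "bias"),
    bias_full_mRR = pick("full", "log_mRR", "bias"),
    bias_be_mRR = pick("backward", "log_mRR", "bias"),
    bias_unadj_mRR = pick("unadjusted", "log_mRR", "bias"),
    rel_eff_cOR = if (!is.null(perf$relative_efficiency))
      perf$relative_efficiency[["log_cOR"]] else NA_real_,
    rel_eff_mRR = if (!is.null(perf$relative_efficiency))
      perf$relative_efficiency[["log_mRR"]] else NA_real_,
    mean_eliminated_confounders = perf$mean_eliminated_confounders,
    n_nonconverged = sum(perf$n_nonconverged),
    ge3_instruments = comp$ge3_instruments,
    ge3_noise = comp$ge3_noise
  )
}

#' Aggregate multi-covariate experiment results into summary-table rows
#'
#' Groups per-scenario result rows by (conditional exposure effect, event
#' fraction, expected events) and computes, per group and overall: mean bias
#' of the full and backward-eliminated models, median/min/max relative
#' efficiency, the number of scenarios in which backward elimination achieved
#' a lower MSE than the full model, and how many of those contained at least
#' three instrumental variables, at least three noise variables, or neither.
#'
#' @param results data.frame of [scenario_results_row()] rows.
#' @param estimand `"cOR"` or `"mRR"`.
#' @param require_complete if a positive integer, error unless every group
#'   contains exactly that many scenarios (495 for the full grid).
#' @return data.frame with one row per group plus an `overall` row.
#' @export
aggregate_exp2 <- function(results, estimand = c("cOR", "mRR"),
                           require_complete = NULL) {
  estimand <- match.arg(estimand)
  bias_full <- results[[paste0("bias_full_", estimand)]]
  bias_be <- results[[paste0("bias_be_", estimand)]]
  rel_eff <- results[[paste0("rel_eff_", estimand)]]

  key <- interaction(results$theta, results$event_fraction,
                     results$expected_events, drop = TRUE)
  if (!is.null(require_complete)) {
    cnt <- table(key)
    bad <- names(cnt)[cnt != require_complete]
    if (length(bad))
      stop("incomplete scenario groups: ", paste(bad, collapse = ", "))
  }
  one <- function(idx, label_theta, label_ef, label_ev) {
    below <- idx[rel_eff[idx] < 1]
    data.frame(
      theta = label_theta, event_fraction = label_ef, expected_events = label_ev,
      n_scenarios = length(idx),
      mean_bias_full = mean(bias_full[idx]),
      mean_bias_be = mean(bias_be[idx]),
      median_rel_eff = stats::median(rel_eff[idx]),
      min_rel_eff = min(rel_eff[idx]),
      max_rel_eff = max(rel_eff[idx]),
      n_be_better = length(below),
      n_be_better_ge3_iv = sum(results$ge3_instruments[below]),
      n_be_better_ge3_noise = sum(results$ge3_noise[below]),
      n_be_better_neither = sum(!results$ge3_instruments[below] &
                                  !results$ge3_noise[below])
    )
  }
  groups <- unique(results[, c("theta", "event_fraction", "expected_events")])
  groups <- groups[order(groups$theta, -groups$event_fraction,
                         groups$expected_events), ]
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    idx <- which(results$theta == groups$theta[g] &
                   results$event_fraction == groups$event_fraction[g] &
                   results$expected_events == groups$expected_events[g])
    one(idx, groups$theta[g], groups$event_fraction[g], groups$expected_events[g])
  })
  overall <- one(seq_len(nrow(results)), NA_real_, NA_real_, NA_real_)
  out <- rbind(do.call(rbind, rows), overall)
  rownames(out) <- NULL
  out
}
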