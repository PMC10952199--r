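#' Conditional log odds ratio of the exposure
#'
#' The exposure coefficient of the fitted outcome model, on the log-odds
#' scale (effects are evaluated on the log scale throughout because of the
#' asymmetry of odds and risk ratios).
#'
#' @param fit a `firth_fit` whose design contains the exposure column.
#' @param exposure name of the exposure column.
#' @return the conditional log odds ratio.
#' @export
conditional_log_or <- function(fit, exposure = "A") {
  if (!exposure %in% colnames(fit$X))
    stop(sprintf("exposure column '%s' is not in the fitted design", exposure))
  unname(fit$coefficients[exposure])
}

#' Standardized marginal effects by g-computation
#'
#' For every subject, predicts the potential-outcome probabilities with the
#' exposure set to 1 and to 0 while keeping the covariates at their observed
#' values, then averages: with \eqn{\bar p_1} and \eqn{\bar p_0} the mean
#' predicted risks, returns \eqn{\log(\bar p_1 / \bar p_0)} (marginal log
#' risk ratio), the log odds ratio of \eqn{\bar p_1} versus \eqn{\bar p_0}
#' (marginal log odds ratio) and \eqn{\bar p_1 - \bar p_0} (marginal risk
#' difference). Predictions should come from a FLIC fit so that predicted
#' risks are calibrated to the observed event fraction.
#'
#' @inheritParams conditional_log_or
#' @return list with `log_mRR`, `log_mOR`, `mRD`.
#' @export
marginal_effects <- function(fit, exposure = "A") {
  if (!exposure %in% colnames(fit$X))
    stop(sprintf("exposure column '%s' is not in the fitted design", exposure))
  X1 <- X0 <- fit$X
  X1[, exposure] <- 1
  X0[, exposure] <- 0
  p1 <- mean(stats::plogis(drop(X1 %*% fit$coefficients)))
  p0 <- mean(stats::plogis(drop(X0 %*% fit$coefficients)))
  if (p0 == 0) stop("mean potential-outcome risk under no exposure is zero")
  list(log_mRR = log(p1 / p0),
       log_mOR = log(p1 / (1 - p1)) - log(p0 / (1 - p0)),
       mRD = p1 - p0)
}

#' All four effect estimates for one dataset under one strategy
#'
#' Strategies: `full` adjusts for all covariates, `backward` runs backward
#' elimination of the candidate covariates first, `unadjusted` fits the
#' exposure-only model. Estimation uses FLIC (Firth slopes, ML-corrected
#' intercept); the conditional log OR is the exposure coefficient and the
#' marginal effects come from g-computation with the same fit.
#'
#' @param dataset a `sim_dataset`.
#' @param strategy one of `"full"`, `"backward"`, `"unadjusted"`.
#' @param alpha backward-elimination removal threshold.
#' @param candidates candidate design columns for backward elimination
#'   (default: all covariates).
#' @return list with `log_cOR`, `log_mRR`, `log_mOR`, `mRD`, `strategy`,
#'   `converged`, `n_covariates` (number retained in the model), and `fit`.
#' @export
estimate_effects <- function(dataset, strategy = c("full", "backward", "unadjusted"),
                             alpha = 0.157, candidates = NULL) {
  strategy <- match.arg(strategy)
  D <- outcome_design(dataset)
  retained <- NULL
  if (strategy == "full") {
    fit <- fit_flic(D, dataset$Y)
    retained <- seq(3L, length.out = ncol(D) - 2L)
  } else if (strategy == "unadjusted") {
    fit <- fit_flic(D[, 1:2, drop = FALSE], dataset$Y)
    retained <- integer(0)
  } else {
    sel <- backward_eliminate(dataset, candidates = candidates, alpha = alpha,
                              fitter = "flic")
    fit <- sel$final_fit
    retained <- sel$retained
  }
  me <- marginal_effects(fit)
  list(log_cOR = conditional_log_or(fit),
       log_mRR = me$log_mRR, log_mOR = me$log_mOR, mRD = me$mRD,
       strategy = strategy, converged = fit$converged,
       n_covariates = length(retained), retained = retained, fit = fit)
}
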