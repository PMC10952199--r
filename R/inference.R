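#' Bootstrap percentile confidence interval
#'
#' Draws `B` resamples of the rows with replacement and forms the percentile
#' interval of the resampled effect estimates (endpoints are order statistics,
#' exactly reproducible given the seed). Three refitting modes mirror the
#' interval constructions contrasted in post-selection inference: `full`
#' refits the full model in every resample; `boot_selected` performs the
#' selection once on the original data and refits only the finally selected
#' covariate set in each resample (the "invalid" selected-model interval);
#' `boot_global` reruns the entire backward elimination inside every resample,
#' propagating selection uncertainty into the interval.
#'
#' @param dataset a `sim_dataset`.
#' @param estimand one of `"log_cOR"`, `"log_mRR"`, `"log_mOR"`, `"mRD"`, or a
#'   function of a resampled dataset returning a scalar (in which case `mode`
#'   is ignored).
#' @param mode `"full"`, `"boot_selected"` or `"boot_global"`.
#' @param B number of resamples (the simulation default is 500).
#' @param level confidence level.
#' @param seed integer seed for the resampling stream.
#' @param alpha backward-elimination threshold for the selection-based modes.
#' @return an object of class `interval_estimate`: list with `lower`, `upper`,
#'   `level`, `method`, `B`, `n_dropped` (non-convergent resamples, which are
#'   discarded) and the vector of resampled `estimates`.
#' @export
bootstrap_ci <- function(dataset, estimand = "log_mRR",
                         mode = c("full", "boot_selected", "boot_global"),
                         B = 500L, level = 0.95, seed = 1L, alpha = 0.157) {
  mode <- match.arg(mode)
  stopifnot(B >= 2L, level > 0, level < 1)
  est_fun <- make_estimand_fn(estimand, mode, dataset, alpha)
  n <- length(dataset$Y)

  est <- with_preserved_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ds_b <- resample_rows(dataset, idx)
      tryCatch(est_fun(ds_b), error = function(e) NA_real_)
    }, numeric(1))
  })
  n_dropped <- sum(!is.finite(est))
  if (n_dropped > 0.1 * B)
    stop(sprintf("%d of %d bootstrap resamples failed to converge", n_dropped, B))
  est <- est[is.finite(est)]
  qs <- stats::quantile(est, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 1, names = FALSE)
  structure(list(lower = qs[1], upper = qs[2], level = level,
                 method = if (is.function(estimand)) "custom" else mode,
                 B = B, n_dropped = n_dropped, estimates = est),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%g%% percentile bootstrap interval (%s, B = %d): [%.4f, %.4f]\n",
              100 * x$level, x$method, x$B, x$lower, x$upper))
  if (x$n_dropped) cat(sprintf("  %d non-convergent resamples dropped\n", x$n_dropped))
  invisible(x)
}

resample_rows <- function(dataset, idx) {
  structure(list(L = dataset$L[idx, , drop = FALSE], A = dataset$A[idx],
                 Y = dataset$Y[idx], scenario_id = dataset$scenario_id,
                 seed = dataset$seed),
            class = "sim_dataset")
}

make_estimand_fn <- function(estimand, mode, dataset, alpha) {
  if (is.function(estimand)) return(estimand)
  stopifnot(estimand %in% c("log_cOR", "log_mRR", "log_mOR", "mRD"))
  if (mode == "full") {
    function(ds) estimate_effects(ds, "full")[[estimand]]
  } else if (mode == "boot_global") {
    function(ds) estimate_effects(ds, "backward", alpha = alpha)[[estimand]]
  } else {
    # selection done once, on the original data
    sel <- backward_eliminate(dataset, alpha = alpha, fitter = "flic")
    cols <- c(1L, 2L, sel$retained)
    function(ds) {
      D <- outcome_design(ds)[, cols, drop = FALSE]
      fit <- fit_flic(D, ds$Y)
      if (!fit$converged) stop("non-convergent resample fit")
      if (estimand == "log_cOR") return(conditional_log_or(fit))
      marginal_effects(fit)[[estimand]]
    }
  }
}

#' Bootstrap stability of backward elimination: RCB and RMSDR
#'
#' Quantifies how much the selection process perturbs the effect estimate,
#' using `B` resamples in which the backward elimination is rerun from
#' scratch ("global" resampling). With \eqn{t_{full}} the full-model estimate
#' on the original data and \eqn{t_b} the globally re-selected estimate in
#' resample b:
#' \itemize{
#'   \item relative conditional bias (percent):
#'     \eqn{RCB = 100 (\bar t_b - t_{full}) / t_{full}};
#'   \item root mean squared difference ratio:
#'     \eqn{RMSDR = \sqrt{\overline{(t_b - t_{full})^2}} / SE_{full}},
#' }
#' where \eqn{SE_{full}} is the full model's standard error of the same
#' estimand: the Wald standard error for the conditional log OR
#' (`se = "model"`), or the bootstrap standard deviation of full-model
#' resample estimates for marginal estimands (`se = "bootstrap"`). RMSDR
#' values above 1 indicate selection-induced variance inflation.
#'
#' @inheritParams bootstrap_ci
#' @param estimand `"log_cOR"` (default), `"log_mRR"`, `"log_mOR"` or `"mRD"`.
#' @param se `"auto"` (model-based for `log_cOR`, bootstrap otherwise),
#'   `"model"` or `"bootstrap"`.
#' @return list with `rcb_percent`, `rmsdr`, `t_full`, `se_full`, `B`,
#'   `n_dropped`.
#' @export
stability_measures <- function(dataset, B = 500L, seed = 1L,
                               estimand = "log_cOR", alpha = 0.157,
                               se = c("auto", "model", "bootstrap")) {
  se <- match.arg(se)
  stopifnot(B >= 2L)
  if (se == "auto") se <- if (estimand == "log_cOR") "model" else "bootstrap"

  full <- estimate_effects(dataset, "full")
  t_full <- full[[estimand]]
  if (t_full == 0) stop("full-model estimate is zero; RCB is undefined")

  n <- length(dataset$Y)
  draws <- with_preserved_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ds_b <- resample_rows(dataset, idx)
      c(sel = tryCatch(estimate_effects(ds_b, "backward", alpha = alpha)[[estimand]],
                       error = function(e) NA_real_),
        full = tryCatch(estimate_effects(ds_b, "full")[[estimand]],
                        error = function(e) NA_real_))
    }, numeric(2)))
  })
  ok <- is.finite(draws[, "sel"]) & is.finite(draws[, "full"])
  n_dropped <- sum(!ok)
  if (n_dropped > 0.1 * B)
    stop(sprintf("%d of %d bootstrap resamples failed to converge", n_dropped, B))
  t_b <- draws[ok, "sel"]

  se_full <- if (se == "model") {
    fit <- full$fit
    j <- match("A", colnames(fit$X))
    if (estimand != "log_cOR")
      stop("model-based SE is only available for the conditional log OR")
    sqrt(fit$covariance[j, j])
  } else {
    stats::sd(draws[ok, "full"])
  }

  list(rcb_percent = 100 * (mean(t_b) - t_full) / t_full,
       rmsdr = sqrt(mean((t_b - t_full)^2)) / se_full,
       t_full = t_full, se_full = se_full, B = B, n_dropped = n_dropped)
}

#' Export interval summaries as CSV
#'
#' Writes rows (estimand, model, estimate, method, lower, upper, width), the
#' layout used to contrast full-model, selected-model and global bootstrap
#' intervals.
#'
#' @param rows data.frame with those columns (width is recomputed).
#' @param path file path.
#' @export
write_ci_summary <- function(rows, path) {
  rows$width <- rows$upper - rows$lower
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
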