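#' Outcome-model design matrix of a dataset
#'
#' Columns: intercept, exposure `A`, covariates `L1..Lp`. The exposure always
#' occupies column 2; covariate j occupies design column j + 2.
#'
#' @param dataset a `sim_dataset` (or any list with `A` and `L`).
#' @return design matrix.
#' @export
outcome_design <- function(dataset) {
  cbind("(Intercept)" = 1, A = dataset$A, dataset$L)
}

#' Backward elimination of candidate confounders
#'
#' Starting from the outcome model containing the exposure and all candidate
#' covariates, repeatedly refits the model and removes the single least
#' significant candidate — the one with the largest penalized
#' likelihood-ratio p-value for dropping it — as long as that p-value exceeds
#' `alpha`. The exposure and intercept are forced to stay. Ties are broken by
#' the lowest column index; removed covariates never re-enter. The default
#' threshold 0.157 approximates selection by the Akaike information
#' criterion.
#'
#' @param dataset a `sim_dataset`.
#' @param candidates design-matrix column indices of the candidate covariates
#'   (covariate j of `L` is design column j + 2). Defaults to all covariates.
#'   Must not contain the intercept (1) or exposure (2) columns.
#' @param alpha removal threshold in (0, 1]; a candidate is removed while its
#'   drop p-value exceeds `alpha`.
#' @param fitter `"flic"` (default) or `"firth"`: how the final model on the
#'   retained set is fitted. Elimination p-values always come from Firth fits.
#' @param p_value `"plr"` (penalized likelihood-ratio, default) or `"wald"`
#'   removal p-values.
#' @return an object of class `selection_result`: list with `retained`
#'   (design indices of retained candidates), `trace` (data.frame step,
#'   column, term, p_value in removal order), `final_fit`, `full_fit`,
#'   `alpha`, `converged`.
#' @export
backward_eliminate <- function(dataset, candidates = NULL, alpha = 0.157,
                               fitter = c("flic", "firth"),
                               p_value = c("plr", "wald")) {
  fitter <- match.arg(fitter)
  p_value <- match.arg(p_value)
  stopifnot(alpha > 0, alpha <= 1)
  D <- outcome_design(dataset)
  if (is.null(candidates)) candidates <- seq(3L, ncol(D))
  candidates <- as.integer(candidates)
  if (any(candidates <= 2L))
    stop("candidates must not include the intercept or exposure columns (1, 2)")
  if (any(candidates > ncol(D)))
    stop("candidate index beyond the design matrix")

  retained <- sort(candidates)
  trace <- data.frame(step = integer(), column = integer(),
                      term = character(), p_value = numeric())
  cur_cols <- c(1L, 2L, retained)
  cur_fit <- fit_firth(D[, cur_cols, drop = FALSE], dataset$Y)
  full_fit <- cur_fit
  step <- 0L
  while (length(retained) > 0L) {
    if (!cur_fit$converged)
      stop(sprintf("Firth fit did not converge at elimination step %d", step))
    pvals <- vapply(seq_along(retained), function(k) {
      j <- 2L + k # position of candidate k in the current design
      if (p_value == "wald") {
        z <- cur_fit$coefficients[j] / sqrt(cur_fit$covariance[j, j])
        return(2 * stats::pnorm(-abs(z)))
      }
      plr_drop_pvalue(cur_fit, j)
    }, numeric(1))
    worst <- which.max(pvals) # which.max takes the first (lowest index) on ties
    if (pvals[worst] <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, column = retained[worst],
      term = colnames(D)[retained[worst]], p_value = pvals[worst]))
    retained <- retained[-worst]
    cur_cols <- c(1L, 2L, retained)
    cur_fit <- fit_firth(D[, cur_cols, drop = FALSE], dataset$Y,
                         beta_init = cur_fit$coefficients[-(2L + worst)])
  }

  final_fit <- if (fitter == "flic") {
    fit_flic(D[, cur_cols, drop = FALSE], dataset$Y, firth = cur_fit)
  } else cur_fit

  structure(list(retained = retained, trace = trace, final_fit = final_fit,
                 full_fit = full_fit, alpha = alpha,
                 converged = final_fit$converged),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("backward elimination (alpha = %.3f): %d candidate(s) removed, %d retained\n",
              x$alpha, nrow(x$trace), length(x$retained)))
  if (nrow(x$trace)) print(x$trace)
  invisible(x)
}

#' Export an elimination trace as CSV
#'
#' @param selection a `selection_result`.
#' @param path file path.
#' @export
write_elimination_trace <- function(selection, path) {
  utils::write.csv(selection$trace[, c("step", "term", "p_value")], path,
                   row.names = FALSE)
  invisible(path)
}
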