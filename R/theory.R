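#' Closed-form bias-variance trade-off for OLS exposure-effect estimation
#'
#' In the linear model \eqn{Y = \theta A + \beta_{LY} L + \varepsilon} with
#' \eqn{Var(\varepsilon) = \sigma^2} and correlated regressors
#' (\eqn{Cor(A, L) = \rho}), the exposure-effect estimator can always include
#' the covariate ("full") or always omit it ("omit"). The standard
#' omitted-variable results give
#' \deqn{bias_{omit} = \beta_{LY} Cov(A, L) / Var(A),}
#' \deqn{Var_{full} = \sigma^2 / \{n Var(A) (1 - \rho^2)\},}
#' \deqn{Var_{omit} = \{\sigma^2 + \beta_{LY}^2 Var(L)(1 - \rho^2)\} / \{n Var(A)\}.}
#' MSE(full) = Var_full (the full model is unbiased); MSE(omit) =
#' bias_omit^2 + Var_omit. Both variances shrink as 1/n while the omission
#' bias does not, so below some sample size the variance saved by omitting
#' the covariate outweighs the squared bias it introduces.
#'
#' @param beta_LY covariate-outcome effect.
#' @param var_A,var_L variances of exposure and covariate (both > 0).
#' @param rho_AL exposure-covariate correlation, |rho| < 1.
#' @param sigma2 residual outcome variance.
#' @param n sample size (>= 3).
#' @return list with `bias_omit`, `var_full`, `var_omit`, `mse_full`,
#'   `mse_omit`.
#' @export
ols_mse_components <- function(beta_LY, var_A, var_L, rho_AL, sigma2, n) {
  stopifnot(var_A > 0, var_L > 0, sigma2 > 0, abs(rho_AL) < 1, n >= 3)
  cov_AL <- rho_AL * sqrt(var_A * var_L)
  bias_omit <- beta_LY * cov_AL / var_A
  var_full <- sigma2 / (n * var_A * (1 - rho_AL^2))
  var_omit <- (sigma2 + beta_LY^2 * var_L * (1 - rho_AL^2)) / (n * var_A)
  list(bias_omit = bias_omit, var_full = var_full, var_omit = var_omit,
       mse_full = var_full, mse_omit = bias_omit^2 + var_omit)
}

#' Crossover sample size of the omitted-variable trade-off
#'
#' The sample size at which the squared omission bias equals the variance
#' saved by omitting the covariate, `bias_omit^2 = var_full(n) -
#' var_omit(n)`. Both variances scale as 1/n, so
#' `n_star = (var_full(1) - var_omit(1)) / bias_omit^2` (a real number);
#' omission lowers the MSE for all n below `n_star`.
#'
#' @inheritParams ols_mse_components
#' @return `n_star` as a double.
#' @section Errors: if omitting the covariate does not reduce the variance at
#'   any sample size (`var_full(1) <= var_omit(1)`), there is no crossover and
#'   an error of class `covselsim_no_crossover` is signaled.
#' @export
crossover_n <- function(beta_LY, var_A, var_L, rho_AL, sigma2) {
  comp <- ols_mse_components(beta_LY, var_A, var_L, rho_AL, sigma2, n = 3)
  if (comp$bias_omit == 0)
    stop("bias_omit is zero; the crossover sample size is undefined")
  var_diff_1 <- 3 * (comp$var_full - comp$var_omit) # rescale to n = 1
  if (var_diff_1 <= 0)
    stop(errorCondition(
      "omitting the covariate never reduces the variance: no crossover",
      class = "covselsim_no_crossover"))
  var_diff_1 / comp$bias_omit^2
}

#' MSE curves over a sample-size range
#'
#' Tabulates MSE(full) and MSE(omit) over `n_grid`, suitable for re-plotting
#' the bias-variance trade-off against sample size.
#'
#' @inheritParams ols_mse_components
#' @param n_grid vector of sample sizes.
#' @return data.frame with columns `n`, `mse_full`, `mse_omit`.
#' @export
ols_tradeoff_curve <- function(beta_LY, var_A, var_L, rho_AL, sigma2,
                               n_grid = 3:200) {
  rows <- lapply(n_grid, function(n) {
    comp <- ols_mse_components(beta_LY, var_A, var_L, rho_AL, sigma2, n)
    data.frame(n = n, mse_full = comp$mse_full, mse_omit = comp$mse_omit)
  })
  do.call(rbind, rows)
}
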