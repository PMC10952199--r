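#' Firth's bias-reduced logistic regression
#'
#' Maximizes the penalized log-likelihood \eqn{\log L(\beta) + \frac{1}{2}\log
#' |I(\beta)|}, where \eqn{I(\beta)} is the Fisher information, by modified
#' Newton scoring with the Firth-adjusted score
#' \deqn{U^*_j = \sum_i \{y_i - \pi_i + h_i(1/2 - \pi_i)\} x_{ij},}
#' \eqn{h_i} being the diagonals of the weighted hat matrix. The penalty
#' removes the leading-order small-sample bias of the maximum-likelihood
#' estimates and guarantees finite coefficients under complete or
#' quasi-complete separation.
#'
#' @param X design matrix (including an intercept column); must have full
#'   column rank.
#' @param y binary response vector (0/1), length `nrow(X)`.
#' @param max_iter maximum number of Newton iterations.
#' @param tol convergence tolerance on the maximum absolute modified score.
#' @param max_halvings maximum step-halvings per iteration; the step is halved
#'   until the penalized likelihood does not decrease.
#' @param beta_init optional starting coefficients (used to warm-start the
#'   many refits done during backward elimination).
#' @return an object of class `firth_fit`: a list with elements
#'   `coefficients`, `covariance` (inverse penalized information at the
#'   optimum), `hat_diagonals`, `penalized_loglik`, `plain_loglik`,
#'   `fitted_probabilities`, `linear_predictors`, `converged`, `n_iterations`,
#'   `method` and the fitting data `X`, `y`.
#' @references Firth D (1993). Bias reduction of maximum likelihood estimates.
#'   Biometrika 80, 27-38. Heinze G, Schemper M (2002). A solution to the
#'   problem of separation in logistic regression. Stat Med 21, 2409-2419.
#' @seealso [fit_flic()] for the intercept-corrected variant used for
#'   probability predictions, [plr_test()], [profile_penalized_likelihood_ci()].
#' @export
fit_firth <- function(X, y, max_iter = 50L, tol = 1e-6, max_halvings = 5L,
                      beta_init = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  beta <- if (is.null(beta_init)) numeric(p) else as.numeric(beta_init)

  state <- firth_state(X, y, beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    if (max(abs(state$score)) < tol) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    delta <- drop(state$Iinv %*% state$score)
    # step-halve until the penalized likelihood is non-decreasing
    step <- 1
    for (hs in 0:max_halvings) {
      cand <- firth_state(X, y, beta + step * delta)
      if (cand$pl >= state$pl - 1e-12) break
      step <- step / 2
    }
    beta <- beta + step * delta
    state <- cand
  }
  if (!converged && max(abs(state$score)) < tol) converged <- TRUE

  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    covariance = state$Iinv,
    hat_diagonals = state$h,
    penalized_loglik = state$pl,
    plain_loglik = state$ll,
    fitted_probabilities = state$pi,
    linear_predictors = state$eta,
    converged = converged,
    n_iterations = iter,
    method = "Firth",
    X = X, y = y
  ), class = "firth_fit")
}

# All per-beta quantities needed by the Newton step, computed in one pass:
# probabilities, weights, hat diagonals, modified score, penalized likelihood.
firth_state <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pi * (1 - pi)
  XW <- X * w
  info <- crossprod(X, XW)
  R <- tryCatch(chol(info), error = function(e) NULL)
  if (is.null(R)) {
    # weights numerically degenerate; ridge the information minimally
    info <- info + diag(1e-10, ncol(X))
    R <- chol(info)
  }
  Iinv <- chol2inv(R)
  h <- rowSums((X %*% Iinv) * XW)
  score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
  ll <- sum(y * eta) - sum(log1pexp(eta))
  pl <- ll + sum(log(diag(R)))
  list(eta = eta, pi = pi, w = w, h = h, score = score,
       Iinv = Iinv, ll = ll, pl = pl)
}

# Penalized log-likelihood at an arbitrary coefficient vector (full design).
penalized_loglik_at <- function(X, y, beta) {
  firth_state(X, y, beta)$pl
}

#' Firth logistic regression with intercept correction (FLIC)
#'
#' Keeps the Firth slope estimates but re-estimates the intercept by ordinary
#' maximum likelihood with the Firth linear predictor (excluding the
#' intercept) as an offset. The ML score equation for a free intercept forces
#' the mean fitted probability to equal the observed event fraction, removing
#' the upward shift in predicted risks that the Firth penalty induces in rare
#' event settings. Slopes are identical to [fit_firth()].
#'
#' @inheritParams fit_firth
#' @param firth optionally, an already computed `fit_firth(X, y)` result.
#' @return a `firth_fit` object with `method = "FLIC"`. The covariance matrix
#'   retains the Firth covariance for the slopes; the intercept variance is
#'   the ML variance of the offset-fixed intercept fit.
#' @references Puhr R, Heinze G, Nold M, Lusa L, Geroldinger A (2017).
#'   Firth's logistic regression with rare events. Stat Med 36, 2302-2317.
#' @export
fit_flic <- function(X, y, max_iter = 50L, tol = 1e-6, firth = NULL) {
  if (is.null(firth)) firth <- fit_firth(X, y, max_iter = max_iter, tol = tol)
  X <- firth$X
  y <- firth$y
  beta <- firth$coefficients
  offset <- if (ncol(X) > 1L) drop(X[, -1L, drop = FALSE] %*% beta[-1L])
            else numeric(nrow(X))

  # Newton for the single free intercept: monotone score sum(y - pi)
  b0 <- beta[1L]
  for (i in 1:50) {
    pi <- stats::plogis(b0 + offset)
    sc <- sum(y - pi)
    if (abs(sc) < 1e-10) break
    b0 <- b0 + sc / sum(pi * (1 - pi))
  }
  beta[1L] <- b0
  st <- firth_state(X, y, beta)
  cov <- firth$covariance
  cov[1L, 1L] <- 1 / sum(st$w) # ML variance of the offset-fixed intercept

  structure(list(
    coefficients = beta,
    covariance = cov,
    hat_diagonals = st$h,
    penalized_loglik = st$pl,
    plain_loglik = st$ll,
    fitted_probabilities = st$pi,
    linear_predictors = st$eta,
    converged = firth$converged && abs(sum(y - st$pi)) < 1e-6,
    n_iterations = firth$n_iterations,
    method = "FLIC",
    X = X, y = y
  ), class = "firth_fit")
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("%s logistic regression (n = %d, %d parameters)\n",
              x$method, length(x$y), length(x$coefficients)))
  se <- sqrt(diag(x$covariance))
  tab <- data.frame(coef = x$coefficients, se = se)
  print(round(tab, 4))
  cat(sprintf("penalized logLik = %.4f, converged = %s (%d iterations)\n",
              x$penalized_loglik, x$converged, x$n_iterations))
  invisible(x)
}

#' Coefficient summary with profile penalized likelihood intervals
#'
#' Plain-text serializable summary table of a Firth/FLIC fit.
#'
#' @param fit a `firth_fit`.
#' @param level confidence level for the intervals.
#' @param ci `"PPL"` for profile penalized likelihood intervals or `"wald"`.
#' @return a data.frame with columns term, estimate, se, lower, upper.
#' @export
summary_table <- function(fit, level = 0.95, ci = c("PPL", "wald")) {
  ci <- match.arg(ci)
  se <- sqrt(diag(fit$covariance))
  p <- length(fit$coefficients)
  if (ci == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- fit$coefficients - z * se
    hi <- fit$coefficients + z * se
  } else {
    lims <- vapply(seq_len(p), function(j) {
      profile_penalized_likelihood_ci(fit$X, fit$y, j, level = level, fit = fit)
    }, numeric(2))
    lo <- lims[1L, ]
    hi <- lims[2L, ]
  }
  data.frame(term = names(fit$coefficients), estimate = unname(fit$coefficients),
             se = unname(se), lower = unname(lo), upper = unname(hi))
}

#' Penalized likelihood-ratio test of nested Firth models
#'
#' Tests the full model against a nested reduced model by refitting the full
#' design with the dropped coefficients constrained to zero, so that both
#' penalized log-likelihoods carry the same (full-design) information
#' penalty; the statistic is twice the difference, floored at zero, and is
#' referred to a chi-squared distribution with degrees of freedom equal to
#' the number of constrained coefficients. (Comparing penalized likelihoods
#' of separately penalized designs would contaminate the statistic with the
#' difference of the two information determinants.)
#'
#' @param fit_full `firth_fit` of the full model.
#' @param fit_reduced `firth_fit` of a model whose columns are a subset of the
#'   full model's, fitted to the same response; identifies which coefficients
#'   are constrained and warm-starts the constrained refit.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
plr_test <- function(fit_full, fit_reduced) {
  full_cols <- colnames(fit_full$X)
  red_cols <- colnames(fit_reduced$X)
  if (!all(red_cols %in% full_cols))
    stop("models are not nested: reduced columns must be a subset of the full model's")
  if (length(fit_full$y) != length(fit_reduced$y) ||
      any(fit_full$y != fit_reduced$y))
    stop("models are not nested: responses differ")
  dropped <- which(!full_cols %in% red_cols)
  df <- length(dropped)
  if (df == 0L) return(list(statistic = 0, df = 0L, p_value = 1))
  start <- numeric(length(full_cols))
  start[match(red_cols, full_cols)] <- fit_reduced$coefficients
  pl0 <- fit_firth_fixed(fit_full$X, fit_full$y, dropped, 0, beta_init = start)
  stat <- max(0, 2 * (fit_full$penalized_loglik - pl0))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Maximize the penalized likelihood over all coefficients except those in
# `fixed_idx`, which are held at `fixed_value`; the penalty uses the FULL
# design information. Used by the profile likelihood CI and the penalized LR
# test. Returns the constrained maximum of the penalized log-likelihood.
# `pl_tol`, if set, additionally stops once a full Newton step improves the
# penalized likelihood by less than pl_tol — enough when only the constrained
# maximum VALUE is needed (likelihood-ratio tests), where near the quadratic
# optimum the remaining gap is of the same order as the last improvement.
fit_firth_fixed <- function(X, y, fixed_idx, fixed_value, beta_init,
                            max_iter = 50L, tol = 1e-6, max_halvings = 5L,
                            pl_tol = NULL) {
  p <- ncol(X)
  free <- setdiff(seq_len(p), fixed_idx)
  beta <- beta_init
  beta[fixed_idx] <- fixed_value
  st <- firth_state(X, y, beta)
  if (length(free) == 0L) return(st$pl)
  Xf <- X[, free, drop = FALSE]
  for (iter in 1:max_iter) {
    sc <- st$score[free]
    if (max(abs(sc)) < tol) break
    info_free <- crossprod(Xf, Xf * st$w)
    delta <- solve(info_free, sc)
    step <- 1
    for (hs in 0:max_halvings) {
      cand_beta <- beta
      cand_beta[free] <- beta[free] + step * delta
      cand <- firth_state(X, y, cand_beta)
      if (cand$pl >= st$pl - 1e-12) break
      step <- step / 2
    }
    improvement <- cand$pl - st$pl
    beta[free] <- beta[free] + step * delta
    st <- cand
    if (!is.null(pl_tol) && step == 1 && abs(improvement) < pl_tol) break
  }
  st$pl
}

# p-value for dropping one column (position `pos`) from a fitted Firth model,
# by the constrained penalized LR test; warm-started at the current estimates.
plr_drop_pvalue <- function(fit, pos) {
  start <- fit$coefficients
  pl0 <- fit_firth_fixed(fit$X, fit$y, pos, 0, beta_init = start,
                         pl_tol = 1e-7)
  stat <- max(0, 2 * (fit$penalized_loglik - pl0))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Profile penalized likelihood confidence interval
#'
#' Interval endpoints are the coefficient values b at which twice the drop
#' from the maximum of the penalized likelihood to the profile penalized
#' likelihood (maximized over all other coefficients with coefficient
#' `coef_index` fixed at b) equals the chi-squared(1) quantile at `level`.
#' Found by bracketing outward from the estimate in Wald-standard-error steps
#' and root-finding. Endpoints are finite even under separation.
#'
#' @param X design matrix.
#' @param y binary response.
#' @param coef_index index of the coefficient to profile.
#' @param level confidence level.
#' @param fit optional precomputed `fit_firth(X, y)`.
#' @param max_steps maximum number of bracket expansions (each of one Wald SE,
#'   doubling) before giving up.
#' @return numeric vector `c(lower, upper)` with attribute `level`.
#' @export
profile_penalized_likelihood_ci <- function(X, y, coef_index, level = 0.95,
                                            fit = NULL, max_steps = 30L) {
  # profiling is anchored at the penalized-likelihood optimum, i.e. the Firth
  # fit; a FLIC fit's intercept is deliberately off-optimum, so refit
  if (is.null(fit) || !identical(fit$method, "Firth")) fit <- fit_firth(X, y)
  if (!fit$converged) stop("profile CI requires a converged fit")
  X <- fit$X
  y <- fit$y
  est <- fit$coefficients[coef_index]
  se <- sqrt(fit$covariance[coef_index, coef_index])
  target <- fit$penalized_loglik - stats::qchisq(level, df = 1) / 2

  # f(b) > 0 inside the interval, < 0 outside
  f <- function(b) {
    fit_firth_fixed(X, y, coef_index, b, beta_init = fit$coefficients) - target
  }
  find_endpoint <- function(direction) {
    step <- se
    b_in <- est
    for (i in seq_len(max_steps)) {
      b_out <- b_in + direction * step
      if (f(b_out) < 0) {
        lims <- sort(c(b_in, b_out))
        return(stats::uniroot(f, lower = lims[1], upper = lims[2],
                              tol = 1e-9)$root)
      }
      b_in <- b_out
      step <- step * 2
    }
    stop(sprintf(
      "profile penalized likelihood does not cross the threshold in [%g, %g]",
      min(est, b_in), max(est, b_in)))
  }
  out <- c(find_endpoint(-1), find_endpoint(1))
  attr(out, "level") <- level
  out
}

#' Wald confidence interval from a Firth/FLIC fit
#'
#' @param fit a `firth_fit`.
#' @param coef_index coefficient index.
#' @param level confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
wald_ci <- function(fit, coef_index, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$coefficients[coef_index]
  se <- sqrt(fit$covariance[coef_index, coef_index])
  unname(c(est - z * se, est + z * se))
}
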