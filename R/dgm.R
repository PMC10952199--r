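#' Scenario grids for the two simulation experiments
#'
#' Scenarios are stored one per row, with the covariate-exposure log odds
#' ratios in columns `bLA1..bLAp` and the covariate-outcome log odds ratios in
#' columns `bLY1..bLYp`. Experiment 1 has a single standard-normal covariate
#' and a null exposure effect; Experiment 2 has 24 equicorrelated
#' standard-normal covariates: 12 fixed weak confounders at
#' (log 1.05, log 1.05) and four exchangeable sets of three covariates, each
#' set assigned one (covariate-exposure, covariate-outcome) pair from
#' \{0, log 1.05, log 1.2\} squared.
#'
#' @name scenarios
NULL

#' Enumerate Experiment 1 scenarios
#'
#' One covariate; exposure effect exactly null; all combinations of
#' `beta_LA`, `beta_LY` over the six-value grid \{0, 0.1, ..., 0.5\} (log-odds
#' scale), sample size 60 or 120, event fraction 0.5 or 0.2: 144 scenarios.
#'
#' @return a data.frame with one row per scenario: `scenario_id`, `theta`,
#'   `n`, `event_fraction`, `rho`, `bLA1`, `bLY1`, and uncalibrated
#'   (`NA`) intercepts `alpha0`, `gamma0`.
#' @export
enumerate_scenarios_exp1 <- function() {
  grid <- expand.grid(
    bLA1 = seq(0, 0.5, by = 0.1),
    bLY1 = seq(0, 0.5, by = 0.1),
    n = c(60L, 120L),
    event_fraction = c(0.5, 0.2),
    KEEP.OUT.ATTRS = FALSE
  )
  data.frame(
    scenario_id = seq_len(nrow(grid)),
    experiment = 1L,
    theta = 0,
    expected_events = grid$n * grid$event_fraction,
    event_fraction = grid$event_fraction,
    n = grid$n,
    rho = 0,
    bLA1 = grid$bLA1,
    bLY1 = grid$bLY1,
    alpha0 = NA_real_,
    gamma0 = NA_real_
  )
}

#' Enumerate Experiment 2 scenarios
#'
#' The four exchangeable mixture sets are canonicalized (sorted by their
#' (beta_LA, beta_LY) pair), so assignments are enumerated as multisets of
#' size 4 over the 9 possible pairs: choose(12, 4) = 495 distinct mixtures.
#' Crossed with conditional exposure effect \{0, log 1.5\}, expected events
#' \{50, 200\} and event fraction \{0.2, 0.03\}: 8 arms x 495 = 3960
#' scenarios. Sample size is `round(expected_events / event_fraction)`, i.e.
#' 250, 1000, 1667 or 6667.
#'
#' @return a data.frame with one row per scenario: `scenario_id`, `theta`,
#'   `expected_events`, `event_fraction`, `n`, `rho`, `bLA1..bLA24`,
#'   `bLY1..bLY24`, and uncalibrated intercepts.
#' @export
enumerate_scenarios_exp2 <- function() {
  pairs <- expand.grid(bLA = c(0, log(1.05), log(1.2)),
                       bLY = c(0, log(1.05), log(1.2)),
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[order(pairs$bLA, pairs$bLY), ]
  # multisets of size 4 over 9 pairs: indices i1 <= i2 <= i3 <= i4
  combos <- utils::combn(9L + 3L, 4L) # combinations of distinct values
  assign_idx <- combos - 0:3          # shift back to non-decreasing multisets
  stopifnot(ncol(assign_idx) == 495L)

  arms <- expand.grid(theta = c(0, log(1.5)),
                      expected_events = c(50L, 200L),
                      event_fraction = c(0.2, 0.03),
                      KEEP.OUT.ATTRS = FALSE)
  n_mix <- ncol(assign_idx)
  n_arm <- nrow(arms)

  fixed_b <- log(1.05)
  bLA_mix <- matrix(pairs$bLA[assign_idx], nrow = 4L) # 4 sets x 495
  bLY_mix <- matrix(pairs$bLY[assign_idx], nrow = 4L)
  # expand sets of three covariates: columns 13..24
  bLA_cov <- apply(bLA_mix, 2L, function(v) rep(v, each = 3L))
  bLY_cov <- apply(bLY_mix, 2L, function(v) rep(v, each = 3L))

  arm_rep <- arms[rep(seq_len(n_arm), each = n_mix), ]
  mix_rep <- rep(seq_len(n_mix), times = n_arm)

  bLA <- cbind(matrix(fixed_b, nrow = n_arm * n_mix, ncol = 12L),
               t(bLA_cov)[mix_rep, , drop = FALSE])
  bLY <- cbind(matrix(fixed_b, nrow = n_arm * n_mix, ncol = 12L),
               t(bLY_cov)[mix_rep, , drop = FALSE])
  colnames(bLA) <- paste0("bLA", 1:24)
  colnames(bLY) <- paste0("bLY", 1:24)

  out <- data.frame(
    scenario_id = seq_len(n_arm * n_mix),
    experiment = 2L,
    theta = arm_rep$theta,
    expected_events = arm_rep$expected_events,
    event_fraction = arm_rep$event_fraction,
    n = as.integer(round(arm_rep$expected_events / arm_rep$event_fraction)),
    rho = 0.3
  )
  out <- cbind(out, bLA, bLY)
  out$alpha0 <- NA_real_
  out$gamma0 <- NA_real_
  rownames(out) <- NULL
  out
}

# extract the beta vectors of one scenario row
scenario_betas <- function(scenario) {
  scenario <- as.list(scenario)
  nm <- names(scenario)
  bla <- nm[grepl("^bLA[0-9]+$", nm)]
  bly <- nm[grepl("^bLY[0-9]+$", nm)]
  bla <- bla[order(as.integer(sub("bLA", "", bla)))]
  bly <- bly[order(as.integer(sub("bLY", "", bly)))]
  list(beta_LA = unlist(scenario[bla], use.names = FALSE),
       beta_LY = unlist(scenario[bly], use.names = FALSE))
}

#' Classify covariates by their causal role
#'
#' Pure function of the two conditional associations: `noise` when both are
#' zero, `instrument` when only the covariate-exposure association is nonzero,
#' `predictor` when only the covariate-outcome association is nonzero, and
#' `confounder` when both are nonzero.
#'
#' @param beta_LA covariate-exposure log odds ratio(s).
#' @param beta_LY covariate-outcome log odds ratio(s).
#' @return character vector of roles.
#' @export
covariate_role <- function(beta_LA, beta_LY) {
  stopifnot(length(beta_LA) == length(beta_LY), all(beta_LA >= 0), all(beta_LY >= 0))
  ifelse(beta_LA == 0 & beta_LY == 0, "noise",
         ifelse(beta_LA > 0 & beta_LY == 0, "instrument",
                ifelse(beta_LA == 0, "predictor", "confounder")))
}

#' Data-generating-mechanism composition of a scenario
#'
#' Role counts and the composition flags used to stratify the Experiment 2
#' summary tables: whether the scenario contains at least three instrumental
#' variables, at least three noise variables, or neither.
#'
#' @param scenario one scenario row (list or single-row data.frame).
#' @return list with `counts` (named role counts), `ge3_instruments`,
#'   `ge3_noise`, `neither`.
#' @export
scenario_composition <- function(scenario) {
  b <- scenario_betas(scenario)
  roles <- covariate_role(b$beta_LA, b$beta_LY)
  counts <- c(confounder = sum(roles == "confounder"),
              instrument = sum(roles == "instrument"),
              predictor = sum(roles == "predictor"),
              noise = sum(roles == "noise"))
  ge3_iv <- counts[["instrument"]] >= 3L
  ge3_noise <- counts[["noise"]] >= 3L
  list(counts = counts, ge3_instruments = ge3_iv, ge3_noise = ge3_noise,
       neither = !ge3_iv && !ge3_noise)
}

# Variances/covariance of the two linear predictors s_A = b_A'L, s_Y = b_Y'L
# under the equicorrelation covariate model Sigma = (1-rho) I + rho J.
lp_moments <- function(beta_LA, beta_LY, rho) {
  v_a <- (1 - rho) * sum(beta_LA^2) + rho * sum(beta_LA)^2
  v_y <- (1 - rho) * sum(beta_LY^2) + rho * sum(beta_LY)^2
  cv <- (1 - rho) * sum(beta_LA * beta_LY) + rho * sum(beta_LA) * sum(beta_LY)
  list(var_a = v_a, var_y = v_y, cov = cv)
}

# Draw (s_A, s_Y) jointly; z1, z2 are iid standard normal base samples.
lp_sample <- function(beta_LA, beta_LY, rho, z1, z2) {
  m <- lp_moments(beta_LA, beta_LY, rho)
  if (m$var_a < .Machine$double.eps) {
    s_a <- numeric(length(z1))
    s_y <- sqrt(m$var_y) * z1
  } else {
    s_a <- sqrt(m$var_a) * z1
    resid <- m$var_y - m$cov^2 / m$var_a
    s_y <- (m$cov / sqrt(m$var_a)) * z1 + sqrt(max(resid, 0)) * z2
  }
  list(s_a = s_a, s_y = s_y)
}

#' Calibrate the exposure- and outcome-model intercepts of a scenario
#'
#' Solves, by monotone root-finding on a fixed-seed Monte-Carlo sample of the
#' covariate linear predictors, for the exposure-model intercept `alpha0` such
#' that the expected exposure prevalence equals `target_exposure_prevalence`,
#' and then for the outcome-model intercept `gamma0` such that the marginal
#' event fraction E\[Y\] equals the scenario's `event_fraction` (integrating
#' analytically over the Bernoulli exposure given the covariates). Under the
#' multivariate-normal covariate model only the joint (bivariate normal)
#' distribution of the two linear predictors matters, so the Monte-Carlo
#' sample is drawn in that two-dimensional space.
#'
#' @param scenario one scenario row.
#' @param target_exposure_prevalence desired Pr(A = 1); the simulation default
#'   is a balanced exposure, 0.5.
#' @param tol calibration tolerance on the probability scale.
#' @param n_mc Monte-Carlo sample size.
#' @param mc_seed fixed seed for the calibration sample.
#' @return named numeric vector `c(alpha0, gamma0)`.
#' @export
calibrate_intercepts <- function(scenario, target_exposure_prevalence = 0.5,
                                 tol = 1e-4, n_mc = 1e6, mc_seed = 20220512L) {
  stopifnot(tol > 0)
  z <- with_preserved_seed(mc_seed, list(z1 = stats::rnorm(n_mc),
                                         z2 = stats::rnorm(n_mc)))
  calibrate_core(scenario, target_exposure_prevalence, tol, z$z1, z$z2)
}

calibrate_core <- function(scenario, target_exposure_prevalence, tol, z1, z2) {
  b <- scenario_betas(scenario)
  s <- lp_sample(b$beta_LA, b$beta_LY, scenario$rho, z1, z2)
  theta <- scenario$theta
  ef <- scenario$event_fraction

  # Newton on the monotone map intercept -> expected probability; `fd` returns
  # both the residual and its derivative. Falls back to bisection-safeguarded
  # bracketing if a step overshoots.
  root <- function(fd, start) {
    x <- start
    lower <- -40; upper <- 40
    for (i in 1:100) {
      v <- fd(x)
      if (abs(v$f) < 1e-12) return(x)
      if (v$f > 0) upper <- x else lower <- x
      x_new <- x - v$f / v$d
      if (!is.finite(x_new) || x_new <= lower || x_new >= upper)
        x_new <- (lower + upper) / 2
      x <- x_new
    }
    stop(sprintf("intercept root-finding did not converge in [%g, %g]",
                 lower, upper))
  }

  alpha0 <- root(function(a) {
    p <- stats::plogis(a + s$s_a)
    list(f = mean(p) - target_exposure_prevalence, d = mean(p * (1 - p)))
  }, start = stats::qlogis(target_exposure_prevalence))
  p_a <- stats::plogis(alpha0 + s$s_a)
  gamma0 <- root(function(g) {
    p1 <- stats::plogis(g + theta + s$s_y)
    p0 <- stats::plogis(g + s$s_y)
    list(f = mean(p_a * p1 + (1 - p_a) * p0) - ef,
         d = mean(p_a * p1 * (1 - p1) + (1 - p_a) * p0 * (1 - p0)))
  }, start = stats::qlogis(ef))

  achieved_a <- mean(stats::plogis(alpha0 + s$s_a))
  achieved_y <- mean(p_a * stats::plogis(gamma0 + theta + s$s_y) +
                       (1 - p_a) * stats::plogis(gamma0 + s$s_y))
  if (abs(achieved_a - target_exposure_prevalence) > tol ||
      abs(achieved_y - ef) > tol)
    stop("intercept calibration did not reach the requested tolerance")
  c(alpha0 = alpha0, gamma0 = gamma0)
}

#' Calibrate every scenario in a grid
#'
#' Fills the `alpha0` and `gamma0` columns of a scenario grid, reusing one
#' fixed-seed Monte-Carlo base sample across scenarios.
#'
#' @inheritParams calibrate_intercepts
#' @param scenarios scenario grid as returned by the `enumerate_scenarios_*`
#'   functions.
#' @return the grid with `alpha0`, `gamma0` filled in.
#' @export
calibrate_scenarios <- function(scenarios, target_exposure_prevalence = 0.5,
                                tol = 1e-4, n_mc = 1e6, mc_seed = 20220512L) {
  z <- with_preserved_seed(mc_seed, list(z1 = stats::rnorm(n_mc),
                                         z2 = stats::rnorm(n_mc)))
  for (i in seq_len(nrow(scenarios))) {
    ab <- calibrate_core(scenarios[i, ], target_exposure_prevalence, tol,
                         z$z1, z$z2)
    scenarios$alpha0[i] <- ab[["alpha0"]]
    scenarios$gamma0[i] <- ab[["gamma0"]]
  }
  scenarios
}

#' Generate one replicate dataset from a calibrated scenario
#'
#' Covariates are multivariate normal with unit variances and constant
#' pairwise correlation `rho` (drawn exactly via a shared standard-normal
#' factor); the binary exposure follows a logistic model in the covariates and
#' the binary outcome a logistic model in exposure and covariates.
#'
#' @param scenario one calibrated scenario row.
#' @param seed integer seed; the same (scenario, seed) always yields the same
#'   dataset, and the caller's RNG state is left untouched.
#' @return an object of class `sim_dataset`: list with `L` (n x p matrix),
#'   `A`, `Y` (binary vectors), `scenario_id`, `seed`.
#' @export
generate_dataset <- function(scenario, seed) {
  if (is.na(scenario$alpha0) || is.na(scenario$gamma0))
    stop("scenario is not calibrated; run calibrate_scenarios() first")
  b <- scenario_betas(scenario)
  n <- scenario$n
  p <- length(b$beta_LA)
  rho <- scenario$rho
  dat <- with_preserved_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p)
    L <- if (rho > 0) {
      sqrt(rho) * stats::rnorm(n) + sqrt(1 - rho) * Z
    } else Z
    A <- stats::rbinom(n, 1L, stats::plogis(scenario$alpha0 + drop(L %*% b$beta_LA)))
    Y <- stats::rbinom(n, 1L, stats::plogis(scenario$gamma0 + scenario$theta * A +
                                              drop(L %*% b$beta_LY)))
    list(L = L, A = A, Y = Y)
  })
  colnames(dat$L) <- paste0("L", seq_len(p))
  structure(list(L = dat$L, A = dat$A, Y = dat$Y,
                 scenario_id = scenario$scenario_id, seed = seed),
            class = "sim_dataset")
}

#' True marginal effects of a scenario by large-sample approximation
#'
#' Draws `approx_N` covariate configurations, computes each subject's
#' potential-outcome probabilities under exposure and no exposure from the
#' true outcome model, and forms the marginal risk ratio, odds ratio and risk
#' difference from the averaged potential-outcome risks. The true conditional
#' log odds ratio is `theta` by construction. A null conditional effect
#' implies exactly null marginal effects (the two potential-outcome
#' probabilities coincide row-wise), so no approximation is used there.
#'
#' @param scenario one calibrated scenario row.
#' @param approx_N size of the large-sample approximation.
#' @param seed seed for the approximation draw.
#' @return list with `log_cOR`, `log_mRR`, `log_mOR`, `mRD`, `approx_N`.
#' @export
true_marginal_effects <- function(scenario, approx_N = 1e6, seed = 907L) {
  theta <- scenario$theta
  if (theta == 0)
    return(list(log_cOR = 0, log_mRR = 0, log_mOR = 0, mRD = 0,
                approx_N = approx_N))
  if (is.na(scenario$gamma0))
    stop("scenario is not calibrated; run calibrate_scenarios() first")
  b <- scenario_betas(scenario)
  m <- lp_moments(b$beta_LA, b$beta_LY, scenario$rho)
  s_y <- with_preserved_seed(seed, sqrt(m$var_y) * stats::rnorm(approx_N))
  p1 <- mean(stats::plogis(scenario$gamma0 + theta + s_y))
  p0 <- mean(stats::plogis(scenario$gamma0 + s_y))
  list(log_cOR = theta,
       log_mRR = log(p1 / p0),
       log_mOR = log(p1 / (1 - p1)) - log(p0 / (1 - p0)),
       mRD = p1 - p0,
       approx_N = approx_N)
}

#' Write or read a scenario grid as CSV
#'
#' One row per scenario with identifiers, design parameters, all beta columns
#' and calibrated intercepts.
#'
#' @param scenarios scenario grid.
#' @param path file path.
#' @return `read_scenarios` returns the grid data.frame.
#' @export
write_scenarios <- function(scenarios, path) {
  utils::write.csv(scenarios, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  utils::read.csv(path)
}

#' Write one dataset as CSV (columns Y, A, L1..Lp) for debugging
#'
#' @param dataset a `sim_dataset`.
#' @param path file path.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(data.frame(Y = dataset$Y, A = dataset$A, dataset$L),
                   path, row.names = FALSE)
  invisible(path)
}
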