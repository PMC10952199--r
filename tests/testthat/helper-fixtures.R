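# Shared fixtures. Everything is generated in code; expensive calibrations are
# cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a hand-built scenario row (single covariate unless p > 1)
make_scenario <- function(theta = 0, beta_LA = 0, beta_LY = 0, n = 100L,
                          event_fraction = 0.5, rho = 0, alpha0 = NA_real_,
                          gamma0 = NA_real_, scenario_id = 999L) {
  p <- max(length(beta_LA), length(beta_LY))
  beta_LA <- rep_len(beta_LA, p)
  beta_LY <- rep_len(beta_LY, p)
  out <- data.frame(scenario_id = scenario_id, experiment = 0L, theta = theta,
                    expected_events = n * event_fraction,
                    event_fraction = event_fraction, n = n, rho = rho)
  for (j in seq_len(p)) out[[paste0("bLA", j)]] <- beta_LA[j]
  for (j in seq_len(p)) out[[paste0("bLY", j)]] <- beta_LY[j]
  out$alpha0 <- alpha0
  out$gamma0 <- gamma0
  out
}

# small calibrated grids reused across test files (reduced MC size: unit tests
# only need the intercepts to be roughly right)
exp1_grid_small <- function() {
  cached("exp1_small", calibrate_scenarios(enumerate_scenarios_exp1(), n_mc = 2e5))
}

exp2_scenario <- function(id, n_mc = 2e5) {
  cached(paste0("exp2_", id, "_", n_mc), {
    grid <- cached("exp2_grid", enumerate_scenarios_exp2())
    calibrate_scenarios(grid[grid$scenario_id == id, , drop = FALSE], n_mc = n_mc)
  })
}

# independent penalized log-likelihood, written against the definition rather
# than the package internals: log L + 0.5 log det(X'WX)
oracle_penalized_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  ll <- sum(y * eta - log(1 + exp(eta)))
  info <- t(X) %*% (X * (p * (1 - p)))
  ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
}

# Brute-force OLS oracle: simulate R replicates of the linear model
# Y = theta*A + beta_LY*L + eps with correlated (A, L), fit both strategies by
# direct least-squares algebra, and return the empirical bias and variances of
# the exposure-effect estimator.
ols_oracle <- function(theta, beta_LY, var_A, var_L, rho_AL, sigma2, n,
                       R = 1e5, seed = 1) {
  set.seed(seed)
  est <- matrix(NA_real_, R, 2)
  for (r in seq_len(R)) {
    zA <- rnorm(n); zL <- rnorm(n)
    A <- sqrt(var_A) * zA
    L <- sqrt(var_L) * (rho_AL * zA + sqrt(1 - rho_AL^2) * zL)
    Y <- theta * A + beta_LY * L + rnorm(n, sd = sqrt(sigma2))
    X <- cbind(1, A, L)
    est[r, 1] <- solve(crossprod(X), crossprod(X, Y))[2]
    Xo <- cbind(1, A)
    est[r, 2] <- solve(crossprod(Xo), crossprod(Xo, Y))[2]
  }
  list(bias_omit = mean(est[, 2]) - theta,
       var_full = var(est[, 1]), var_omit = var(est[, 2]),
       se_bias = sd(est[, 2]) / sqrt(R),
       se_var_full = sd((est[, 1] - mean(est[, 1]))^2) / sqrt(R),
       se_var_omit = sd((est[, 2] - mean(est[, 2]))^2) / sqrt(R))
}

# maximize the oracle penalized likelihood on a grid (1 or 2 parameters)
oracle_grid_max <- function(X, y, grids) {
  pts <- as.matrix(expand.grid(grids))
  vals <- apply(pts, 1L, function(b) oracle_penalized_loglik(X, y, b))
  pts[which.max(vals), ]
}
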