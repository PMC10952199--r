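test_that("intercept-only Firth estimates follow the (k + 1/2)/(n + 1) closed form", {
  cases <- list(c(k = 3, n = 6), c(k = 0, n = 4), c(k = 2, n = 9), c(k = 7, n = 7))
  for (cs in cases) {
    y <- rep(c(1, 0), c(cs[["k"]], cs[["n"]] - cs[["k"]]))
    X <- matrix(1, cs[["n"]], 1, dimnames = list(NULL, "(Intercept)"))
    fit <- fit_firth(X, y, tol = 1e-10)
    expect_equal(unname(fit$coefficients),
                 qlogis((cs[["k"]] + 0.5) / (cs[["n"]] + 1)), tolerance = 1e-8)
    expect_true(fit$converged)
  }
})

test_that("degenerate all-0 and all-1 responses still give finite estimates", {
  X <- matrix(1, 5, 1)
  expect_equal(unname(fit_firth(X, rep(0, 5), tol = 1e-10)$coefficients),
               qlogis(0.5 / 6), tolerance = 1e-8)
  expect_equal(unname(fit_firth(X, rep(1, 5), tol = 1e-10)$coefficients),
               qlogis(5.5 / 6), tolerance = 1e-8)
})

test_that("Newton optimum matches an independent grid/optim maximization", {
  # 1-parameter model, 0 events of 4: grid oracle
  X1 <- matrix(1, 4, 1)
  y1 <- rep(0, 4)
  b_grid <- oracle_grid_max(X1, y1, list(seq(-4, 0, by = 1e-4)))
  fit1 <- fit_firth(X1, y1, tol = 1e-10)
  expect_equal(unname(fit1$coefficients), unname(b_grid), tolerance = 1e-4)

  # 2-parameter separated model: symmetry forces intercept 0, slope finite
  X2 <- cbind("(Intercept)" = 1, x = c(-2, -1, 1, 2))
  y2 <- c(0, 0, 1, 1)
  fit2 <- fit_firth(X2, y2, tol = 1e-10)
  expect_true(all(is.finite(fit2$coefficients)))
  expect_equal(unname(fit2$coefficients[1]), 0, tolerance = 1e-6)
  b2 <- oracle_grid_max(X2, y2, list(seq(-0.2, 0.2, by = 0.01),
                                     seq(0.5, 1.5, by = 1e-3)))
  expect_equal(unname(fit2$coefficients[2]), unname(b2[2]), tolerance = 1e-3)

  # random non-separated 2-parameter fit against optim
  set.seed(11)
  x <- rnorm(40)
  y <- rbinom(40, 1, plogis(0.5 * x))
  X3 <- cbind("(Intercept)" = 1, x = x)
  fit3 <- fit_firth(X3, y, tol = 1e-10)
  o <- optim(c(0, 0), function(b) -oracle_penalized_loglik(X3, y, b),
             method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(fit3$coefficients), o$par, tolerance = 1e-4)
})

test_that("hat diagonals lie in [0,1] and sum to the parameter count", {
  set.seed(21)
  for (p_cov in c(1, 3, 6)) {
    n <- 120
    L <- matrix(rnorm(n * p_cov), n)
    y <- rbinom(n, 1, plogis(0.3 * L[, 1]))
    X <- cbind(1, L)
    fit <- fit_firth(X, y)
    expect_true(all(fit$hat_diagonals >= 0 & fit$hat_diagonals <= 1))
    expect_equal(sum(fit$hat_diagonals), ncol(X), tolerance = 1e-8)
    expect_true(all(fit$fitted_probabilities > 0 & fit$fitted_probabilities < 1))
  }
})

test_that("Wald covariance agrees with numerically differentiated information", {
  set.seed(31)
  n <- 80
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_firth(X, y, tol = 1e-10)
  # numerical Hessian of the plain log-likelihood at the optimum
  eps <- 1e-5
  ll <- function(b) sum(y * drop(X %*% b) - log(1 + exp(drop(X %*% b))))
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- eps; ej[j] <- eps
    H[i, j] <- (ll(fit$coefficients + ei + ej) - ll(fit$coefficients + ei) -
                  ll(fit$coefficients + ej) + ll(fit$coefficients)) / eps^2
  }
  expect_equal(unname(fit$covariance), solve(-H), tolerance = 1e-3)
})

test_that("rank-deficient designs are rejected with the collinear columns named", {
  X <- cbind("(Intercept)" = 1, a = 1:6, twice_a = 2 * (1:6))
  expect_error(fit_firth(X, rep(0:1, 3)), "twice_a")
})

test_that("Firth estimates approach ML estimates as n grows", {
  gaps <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.5 * x))
    X <- cbind(1, x)
    firth <- fit_firth(X, y)$coefficients
    ml <- coef(glm.fit(X, y, family = binomial()))
    max(abs(firth - ml))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  # O(1/n): hundredfold n should shrink the gap by well over a factor 10
  expect_lt(gaps[3], gaps[1] / 10)
})

test_that("FLIC keeps Firth slopes and calibrates the mean fitted probability", {
  set.seed(41)
  n <- 150
  L <- matrix(rnorm(n * 2), n)
  A <- rbinom(n, 1, plogis(0.4 * L[, 1]))
  y <- rbinom(n, 1, plogis(-2 + 0.4 * A + 0.5 * L[, 1]))
  X <- cbind("(Intercept)" = 1, A = A, L1 = L[, 1], L2 = L[, 2])
  firth <- fit_firth(X, y)
  flic <- fit_flic(X, y)
  expect_identical(unname(flic$coefficients[-1]), unname(firth$coefficients[-1]))
  expect_equal(mean(flic$fitted_probabilities), mean(y), tolerance = 1e-8)
  # intercept-only FLIC is plain ML
  X0 <- matrix(1, n, 1)
  expect_equal(unname(fit_flic(X0, y)$coefficients), qlogis(mean(y)),
               tolerance = 1e-8)
})

test_that("penalized LR test is null on identical models and chi-squared calibrated", {
  set.seed(51)
  n <- 60
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_firth(X, y)
  same <- plr_test(fit, fit)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # df = 1, statistic 3.841 -> p ~ 0.05 (quantile identity on the reference dist)
  expect_equal(pchisq(qchisq(0.95, 1), 1, lower.tail = FALSE), 0.05)

  # dropping a strong covariate is detected
  set.seed(52)
  n <- 500
  z <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(-0.5 + 1 * z))
  Xf <- cbind("(Intercept)" = 1, z = z)
  Xr <- Xf[, 1, drop = FALSE]
  tst <- plr_test(fit_firth(Xf, y2), fit_firth(Xr, y2))
  expect_equal(tst$df, 1)
  expect_lt(tst$p_value, 0.001)

  expect_error(plr_test(fit_firth(Xr, y2), fit_firth(Xf, y2)), "nested")
})

test_that("profile penalized likelihood interval inverts its defining equation", {
  set.seed(61)
  n <- 50
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.7 * x))
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_firth(X, y, tol = 1e-10)
  ci <- profile_penalized_likelihood_ci(X, y, 2, level = 0.95, fit = fit)
  expect_lt(ci[1], fit$coefficients[2])
  expect_gt(ci[2], fit$coefficients[2])
  drop_at <- function(b) {
    2 * (fit$penalized_loglik -
           covselsim:::fit_firth_fixed(X, y, 2L, b, fit$coefficients))
  }
  expect_equal(drop_at(ci[1]), qchisq(0.95, 1), tolerance = 1e-6)
  expect_equal(drop_at(ci[2]), qchisq(0.95, 1), tolerance = 1e-6)

  # balanced intercept-only interval is symmetric about zero
  X0 <- matrix(1, 6, 1)
  y0 <- rep(c(0, 1), 3)
  ci0 <- profile_penalized_likelihood_ci(X0, y0, 1, level = 0.95)
  expect_equal(ci0[1], -ci0[2], tolerance = 1e-6)

  # finite on both sides under complete separation
  Xs <- cbind("(Intercept)" = 1, x = c(-2, -1, 1, 2))
  cis <- profile_penalized_likelihood_ci(Xs, c(0, 0, 1, 1), 2)
  expect_true(all(is.finite(cis)))
})

test_that("penalized likelihood at the optimum dominates a surrounding grid", {
  set.seed(71)
  n <- 30
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 - x))
  X <- cbind(1, x)
  fit <- fit_firth(X, y, tol = 1e-10)
  grid <- expand.grid(d1 = seq(-0.5, 0.5, by = 0.1), d2 = seq(-0.5, 0.5, by = 0.1))
  vals <- apply(grid, 1, function(d) {
    oracle_penalized_loglik(X, y, fit$coefficients + d)
  })
  expect_true(all(vals <= oracle_penalized_loglik(X, y, fit$coefficients) + 1e-10))
})
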