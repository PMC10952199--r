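test_that("scenario enumeration is exhaustive, deterministic and well-formed", {
  s1 <- enumerate_scenarios_exp1()
  expect_identical(nrow(s1), 144L)
  expect_true(all(s1$theta == 0))
  expect_true(all(s1$bLA1 >= 0 & s1$bLA1 <= 0.5))
  expect_true(any(s1$bLA1 == 0 & s1$bLY1 == 0)) # pure-noise covariate present
  expect_identical(s1, enumerate_scenarios_exp1()) # order-stable

  s2 <- enumerate_scenarios_exp2()
  expect_identical(nrow(s2), 3960L)
  expect_identical(s2, enumerate_scenarios_exp2())
  expect_true(all(s2$n %in% c(250L, 1000L, 1667L, 6667L)))
  # 495 distinct mixture assignments per arm, and no duplicated scenarios
  arm <- s2[s2$theta == 0 & s2$expected_events == 50 & s2$event_fraction == 0.2, ]
  expect_identical(nrow(arm), 495L)
  beta_cols <- grep("^bL", names(s2), value = TRUE)
  expect_false(any(duplicated(s2[, c("theta", "expected_events",
                                     "event_fraction", beta_cols)])))
  # the first 12 covariates are always the fixed weak confounders
  expect_true(all(s2$bLA1 == log(1.05)) && all(s2$bLY12 == log(1.05)))
})

test_that("covariate roles are a pure function of the association pair", {
  expect_identical(
    covariate_role(c(0, 0.1, 0, 0.2), c(0, 0, 0.1, 0.2)),
    c("noise", "instrument", "predictor", "confounder"))
  # role composition is computable from the scenario alone
  s2 <- enumerate_scenarios_exp2()
  comp <- scenario_composition(s2[1, ])
  expect_identical(sum(comp$counts), 24L)
  expect_gte(comp$counts[["confounder"]], 12L)
})

test_that("intercept calibration hits its targets on an independent sample", {
  # closed forms when all associations vanish
  null_sc <- make_scenario(event_fraction = 0.5)
  ab <- calibrate_intercepts(null_sc, n_mc = 1e5)
  expect_equal(ab[["gamma0"]], 0, tolerance = 1e-9)
  ab2 <- calibrate_intercepts(make_scenario(event_fraction = 0.2), n_mc = 1e5)
  expect_equal(ab2[["gamma0"]], qlogis(0.2), tolerance = 1e-9)

  # a rare-event multi-covariate scenario, verified on an independent draw
  sc <- exp2_scenario(495 * 5 + 100, n_mc = 1e6) # theta = log(1.5), ef = 0.03
  b <- covselsim:::scenario_betas(sc)
  set.seed(424242) # independent of the calibration seed
  z1 <- rnorm(1e6); z2 <- rnorm(1e6)
  s <- covselsim:::lp_sample(b$beta_LA, b$beta_LY, sc$rho, z1, z2)
  p_a <- plogis(sc$alpha0 + s$s_a)
  expect_equal(mean(p_a), 0.5, tolerance = 1e-3)
  p_y <- p_a * plogis(sc$gamma0 + sc$theta + s$s_y) +
    (1 - p_a) * plogis(sc$gamma0 + s$s_y)
  mc_se <- sd(p_y) / sqrt(length(p_y))
  expect_lt(abs(mean(p_y) - 0.03), 1e-4 + 4 * mc_se)
})

test_that("dataset generation is reproducible and matches the covariate model", {
  sc <- exp1_grid_small()[10, ]
  d1 <- generate_dataset(sc, seed = 99)
  d2 <- generate_dataset(sc, seed = 99)
  expect_identical(d1, d2)
  expect_true(all(d1$A %in% 0:1) && all(d1$Y %in% 0:1))
  expect_true(all(is.finite(d1$L)))

  # empirical pairwise covariate correlation on a large draw: 0.3 +- 0.005
  big <- exp2_scenario(1)
  big$n <- 400000L
  dl <- generate_dataset(big, seed = 7)
  cors <- cor(dl$L[, c(1, 8, 17, 24)])
  expect_equal(unname(cors[upper.tri(cors)]), rep(0.3, 6), tolerance = 0.005)

  # marginal event fraction across replicates matches the calibrated target
  sc2 <- exp2_scenario(1) # ef = 0.2, n = 250
  ys <- vapply(1:120, function(s) mean(generate_dataset(sc2, seed = s)$Y),
               numeric(1))
  mc_se <- sd(ys) / sqrt(length(ys))
  expect_equal(mean(ys), 0.2, tolerance = 4 * mc_se + 0.005)
})

test_that("uncalibrated scenarios are refused", {
  expect_error(generate_dataset(make_scenario(), seed = 1), "calibrat")
})

test_that("large-sample true effects match closed forms and noncollapsibility", {
  # null conditional effect: all marginal effects exactly zero
  tr0 <- true_marginal_effects(make_scenario(theta = 0))
  expect_identical(unlist(tr0[c("log_mRR", "log_mOR", "mRD")]),
                   c(log_mRR = 0, log_mOR = 0, mRD = 0))

  # no covariate-outcome effects, gamma0 = 0, theta = log 1.5: closed form
  sc <- make_scenario(theta = log(1.5), beta_LA = 0.3, beta_LY = 0,
                      alpha0 = 0, gamma0 = 0)
  tr <- true_marginal_effects(sc)
  expect_equal(tr$log_mRR, log(1.2), tolerance = 1e-12)
  expect_equal(tr$log_mOR, log(1.5), tolerance = 1e-12)
  expect_equal(tr$mRD, 0.1, tolerance = 1e-12)

  # nonzero covariate-outcome effect attenuates the marginal OR (noncollapsibility)
  sc2 <- make_scenario(theta = log(1.5), beta_LA = 0.2, beta_LY = 0.8,
                       alpha0 = 0, gamma0 = -1)
  tr2 <- true_marginal_effects(sc2)
  expect_lt(abs(tr2$log_mOR), log(1.5))
  expect_gt(tr2$log_mOR, 0) # same sign as theta
  expect_gt(tr2$log_mRR, 0)
})

test_that("scenario grids round-trip through CSV", {
  s1 <- calibrate_scenarios(enumerate_scenarios_exp1()[1:3, ], n_mc = 1e4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenarios(s1, path)
  back <- read_scenarios(path)
  expect_equal(back$alpha0, s1$alpha0, tolerance = 1e-12)
  expect_identical(back$scenario_id, s1$scenario_id)

  ds <- generate_dataset(s1[1, ], seed = 3)
  dpath <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, dpath)
  dd <- utils::read.csv(dpath)
  expect_identical(names(dd), c("Y", "A", "L1"))
  expect_identical(nrow(dd), s1$n[1])
})
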