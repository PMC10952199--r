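test_that("per-scenario Monte-Carlo summaries obey their algebraic identities", {
  sc <- exp1_grid_small()[40, ]
  perf <- run_scenario(sc, n_reps = 60, strategies = c("full", "unadjusted"),
                       root_seed = 7)
  p <- perf$performance
  expect_true(all(p$n_effective <= 60))
  # mse = bias^2 + variance, all three computed from the same replicate vector
  expect_equal(p$mse, p$bias^2 + p$variance, tolerance = 1e-12)
  expect_true(all(p$variance >= 0))
  # rerunning with the same root seed reproduces results bitwise
  perf2 <- run_scenario(sc, n_reps = 60, strategies = c("full", "unadjusted"),
                        root_seed = 7)
  expect_identical(perf$performance, perf2$performance)
})

test_that("replicate seed streams make results independent of execution order", {
  sc <- exp1_grid_small()[40, ]
  # the r-th replicate dataset depends only on (root_seed, scenario_id, r)
  d3 <- generate_dataset(sc, derive_seed(7, sc$scenario_id, 3))
  perf <- run_scenario(sc, n_reps = 3, strategies = "full", root_seed = 7)
  d3b <- generate_dataset(sc, derive_seed(7, sc$scenario_id, 3))
  expect_identical(d3, d3b)
})

test_that("the bias-variance inequality check is a pure arithmetic predicate", {
  fake <- structure(list(performance = data.frame(
    strategy = rep(c("full", "unadjusted"), each = 1),
    estimand = "log_cOR",
    bias = c(0, 0), variance = c(0.5, 0.3), mse = c(0.5, 0.3),
    n_effective = 100)), class = "scenario_performance")
  expect_true(inequality_check(fake, "log_cOR"))
  fake$performance$bias[2] <- 1 # large omission bias, equal variances
  fake$performance$variance <- c(0.4, 0.4)
  expect_false(inequality_check(fake, "log_cOR"))
})

test_that("aggregation reproduces the summary-table layout and subset counts", {
  s2 <- enumerate_scenarios_exp2()
  ids <- c(1:6, 496:501, 991:996, 1486:1491, 1981:1986, 2476:2481,
           2971:2976, 3466:3471)
  sub <- s2[s2$scenario_id %in% ids, ]
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    sc <- sub[i, ]
    comp <- scenario_composition(sc)
    data.frame(scenario_id = sc$scenario_id, theta = sc$theta,
               event_fraction = sc$event_fraction,
               expected_events = sc$expected_events, n = sc$n,
               bias_full_cOR = 0.001, bias_be_cOR = 0.03,
               bias_unadj_cOR = 0.5, bias_full_mRR = 0.001,
               bias_be_mRR = 0.02, bias_unadj_mRR = 0.5,
               rel_eff_cOR = 1.08, rel_eff_mRR = 1.08,
               mean_eliminated_confounders = 1, n_nonconverged = 0,
               ge3_instruments = comp$ge3_instruments,
               ge3_noise = comp$ge3_noise)
  })
  results <- do.call(rbind, rows)
  tab <- aggregate_exp2(results, "cOR")
  expect_identical(nrow(tab), 9L) # 8 groups + overall
  # constant relative efficiency: median = min = max, none below 1
  expect_true(all(tab$median_rel_eff == 1.08 & tab$min_rel_eff == 1.08 &
                    tab$max_rel_eff == 1.08))
  expect_true(all(tab$n_be_better == 0))
  # composition columns can never exceed the below-1 count
  results$rel_eff_cOR <- ifelse(results$scenario_id %% 2 == 0, 0.98, 1.05)
  tab2 <- aggregate_exp2(results, "cOR")
  expect_true(all(tab2$n_be_better_ge3_iv <= tab2$n_be_better))
  expect_true(all(tab2$n_be_better_ge3_noise <= tab2$n_be_better))
  expect_true(all(tab2$n_be_better_neither <= tab2$n_be_better))
  # completeness check
  expect_error(aggregate_exp2(results[-1, ], "cOR", require_complete = 6),
               "incomplete")
})

test_that("degenerate replicate counts are handled per contract", {
  sc <- exp1_grid_small()[1, ]
  expect_error(run_scenario(sc, n_reps = 1), "n_reps")
  perf <- run_scenario(sc, n_reps = 2, strategies = "full", root_seed = 5)
  expect_true(all(perf$performance$n_effective == 2))
})

test_that("backward elimination counts eliminated true confounders", {
  sc <- exp2_scenario(40)
  perf <- run_scenario(sc, n_reps = 4, strategies = c("full", "backward"),
                       root_seed = 2)
  expect_true(is.finite(perf$mean_eliminated_confounders))
  expect_gte(perf$mean_eliminated_confounders, 0)
  expect_true(all(c("log_cOR", "log_mRR") %in%
                    names(perf$relative_efficiency)))
  expect_true(all(perf$relative_efficiency > 0))
})

test_that("coverage bookkeeping records Wald, PPL and bootstrap intervals", {
  sc <- exp1_grid_small()[1, ]
  perf <- run_scenario(sc, n_reps = 3, strategies = "full", root_seed = 9,
                       coverage = TRUE, boot_B = 30)
  expect_false(is.null(perf$coverage))
  expect_true(all(perf$coverage[, -1] >= 0 & perf$coverage[, -1] <= 1))
})
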