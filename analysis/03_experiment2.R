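#!/usr/bin/env Rscript
# Experiment 2: 24 correlated covariates, full model vs backward elimination
# vs no adjustment. Produces one summary row per scenario (biases, relative
# efficiencies, composition flags). The full 3960-scenario grid at 50-100
# replicates per scenario is an overnight single-CPU run (or a few hours
# parallelised by splitting the id range across processes); the full-scale
# design uses 1000 replicates per scenario.
#
# Usage: Rscript analysis/03_experiment2.R [reps] [seed] [id_from] [id_to]
#   defaults: reps 50, seed 1, the whole grid. Output is appended per
#   scenario to results/experiment2_results.csv, so interrupted runs resume
#   by rerunning with the remaining id range.

library(covselsim)

args <- commandArgs(trailingOnly = TRUE)
reps <- if (length(args) >= 1) as.integer(args[1]) else 50L
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L
id_from <- if (length(args) >= 3) as.integer(args[3]) else 1L
id_to <- if (length(args) >= 4) as.integer(args[4]) else NA_integer_
dir.create("results", showWarnings = FALSE)

scen <- if (file.exists("results/scenarios_exp2.csv")) {
  read_scenarios("results/scenarios_exp2.csv")
} else {
  message("Calibrating the grid first (about an hour); persist it with ",
          "analysis/01_scenarios.R --exp2 to skip this next time.")
  calibrate_scenarios(enumerate_scenarios_exp2())
}
if (is.na(id_to)) id_to <- max(scen$scenario_id)

out_path <- "results/experiment2_results.csv"
done <- if (file.exists(out_path)) utils::read.csv(out_path)$scenario_id else integer(0)
todo <- scen$scenario_id[scen$scenario_id >= id_from & scen$scenario_id <= id_to &
                           !scen$scenario_id %in% done]
message(sprintf("%d scenarios to run at %d replicates each (seed %d)",
                length(todo), reps, seed))

for (id in todo) {
  sc <- scen[scen$scenario_id == id, ]
  perf <- run_scenario(sc, n_reps = reps,
                       strategies = c("full", "backward", "unadjusted"),
                       root_seed = seed)
  row <- scenario_results_row(sc, perf)
  utils::write.table(row, out_path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(out_path), append = file.exists(out_path))
  if (id %% 20 == 0) message(sprintf("  scenario %d / %d done", id, id_to))
}
message("Per-scenario results: ", out_path)
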