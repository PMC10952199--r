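#!/usr/bin/env Rscript
# Enumerate and calibrate both scenario grids, and persist them as CSV.
#
# The single-covariate grid (144 scenarios) calibrates in about a minute; the
# multi-covariate grid (3960 scenarios) takes on the order of an hour because
# every scenario solves two intercept calibrations on a 1e6-draw sample.
# Usage: Rscript analysis/01_scenarios.R [--exp2]

library(covselsim)

args <- commandArgs(trailingOnly = TRUE)
dir.create("results", showWarnings = FALSE)

message("Calibrating the 144 single-covariate scenarios ...")
exp1 <- calibrate_scenarios(enumerate_scenarios_exp1())
write_scenarios(exp1, "results/scenarios_exp1.csv")
message("  -> results/scenarios_exp1.csv (", nrow(exp1), " scenarios)")

if ("--exp2" %in% args) {
  message("Calibrating the 3960 multi-covariate scenarios (slow) ...")
  exp2 <- calibrate_scenarios(enumerate_scenarios_exp2())
  write_scenarios(exp2, "results/scenarios_exp2.csv")
  message("  -> results/scenarios_exp2.csv (", nrow(exp2), " scenarios)")
} else {
  message("Skipping the multi-covariate grid (pass --exp2 to calibrate it).")
}
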