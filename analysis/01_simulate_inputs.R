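#!/usr/bin/env Rscript
# Stage 1 — generate every input the pipeline needs, with sidecar truth
# files so later stages can be checked against the generating values:
#   - discrete-choice responses at the study geometry (256 respondents,
#     6 tasks each, two services + opt-out per task)
#   - a two-arm trial-like payoff summary (cycle costs, EQ-5D utilities)
#   - a synthetic life table (all-cause and respiratory mortality)

suppressPackageStartupMessages(library(breathcea))

seed <- 20260921
out_dir <- file.path("results", "inputs")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- default_attributes()
truth <- synthetic_truth(design)

dce <- simulate_choice_data(design, truth, n_respondents = 256,
                            n_tasks = 6, seed = seed)
write_choice_csv(dce, file.path(out_dir, "choice_data.csv"))
write_design_config(design, file.path(out_dir, "service_attributes.yaml"))

trial <- synth_trial_payoffs(seed = seed + 1)
jsonlite::write_json(
  list(params = trial$payoffs$params, arms = trial$arms),
  file.path(out_dir, "trial_payoffs.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

life_table <- synth_life_table()
write_life_table(life_table, file.path(out_dir, "life_table.csv"))

write_synthetic_truth(file.path(out_dir, "truth_sidecar.json"),
                      truth = truth, payoff_truth = trial$truth,
                      seed = seed)

cc <- choice_counts(dce)
cat("simulated choice data:", cc$n_tasks, "tasks,", cc$n_observations,
    "observations from", cc$n_respondents, "respondents\n")
cat("opt-out chosen in", sprintf("%.1f%%", 100 * mean(
  dce$chosen[dce$is_opt_out == 1])), "of tasks\n")
cat("trial payoffs: control cost",
    sprintf("%.0f", trial$arms$control$cost_mean), "GBP/cycle, effect cost",
    sprintf("%.0f", trial$arms$effect$cost_mean), "GBP/cycle\n")
cat("inputs written to", out_dir, "\n")
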