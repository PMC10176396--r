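#!/usr/bin/env Rscript
# Stage 5 — probabilistic sensitivity analysis (1000 Monte Carlo draws over
# the payoff inputs) and the cost-effectiveness acceptability curve against
# willingness to pay (£0–£50,000 per QALY).

suppressPackageStartupMessages(library(breathcea))

seed <- 20260925
coeffs <- read_coefficients(file.path("results",
                                      "fitted_coefficients.json"))
life_table <- read_life_table(file.path("results", "inputs",
                                        "life_table.csv"))
pj <- jsonlite::read_json(file.path("results", "inputs",
                                    "trial_payoffs.json"),
                          simplifyVector = TRUE)
pp <- pj$params
payoffs <- ce_payoffs(
  control_cost = pp$mean[pp$param == "cost_control"],
  control_utility = pp$mean[pp$param == "utility_control"],
  effect_cost = pp$mean[pp$param == "cost_effect"],
  effect_utility = pp$mean[pp$param == "utility_effect"],
  control_cost_var = pp$var[pp$param == "cost_control"],
  control_utility_var = pp$var[pp$param == "utility_control"],
  effect_cost_var = pp$var[pp$param == "cost_effect"],
  effect_utility_var = pp$var[pp$param == "utility_effect"])

most <- service_config(place = "outpatient_clinic",
                       review = "comprehensive",
                       support = "therapists_and_social_worker",
                       waiting = "2_weeks")
cohort <- cohort_spec(uptake = uptake_probability(coeffs, most)$probability)

for (arm in c("bs", "bs_extended")) {
  psa <- draw_psa(cohort, life_table, payoffs, intervention = arm,
                  n = 1000, seed = seed)
  utils::write.csv(psa$draws,
                   file.path("results", sprintf("psa_draws_%s.csv", arm)),
                   row.names = FALSE)
  curve <- ceac(psa)
  utils::write.csv(as.data.frame(curve),
                   file.path("results", sprintf("ceac_%s.csv", arm)),
                   row.names = FALSE)
  print(psa)
  cat(sprintf(
    "  %s: %.1f%% of draws dominant; acceptability %s across £0–£50k/QALY\n",
    arm,
    100 * mean(psa$draws$delta_cost < 0 & psa$draws$delta_qaly > 0),
    if (all(curve$acceptability == 1)) "= 1 (complete acceptance)"
    else sprintf("in [%.2f, %.2f]", min(curve$acceptability),
                 max(curve$acceptability))))
}
cat("PSA draws and CEAC curves written to results/\n")
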