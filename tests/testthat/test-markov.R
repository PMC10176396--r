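test_that("discounting and probability conversion match closed forms", {
  expect_equal(per_cycle_discount(0, 0.035), 1.0, tolerance = 1e-12)
  expect_equal(per_cycle_discount(4, 0.035), 1 / 1.035, tolerance = 1e-12)
  expect_equal(per_cycle_discount(20, 0.035), 1.035^-5, tolerance = 1e-12)
  expect_error(per_cycle_discount(-1, 0.035), ">= 0")

  expect_equal(annual_to_cycle_probability(0), 0)
  expect_equal(annual_to_cycle_probability(1), 1)
  expect_equal(annual_to_cycle_probability(0.04), 1 - 0.96^0.25,
               tolerance = 1e-12)
  expect_error(annual_to_cycle_probability(1.2), "outside")
})

test_that("full survival, utility one and no discounting yields exactly
           five QALYs over the horizon", {
  tr <- run_cohort(cohort_spec(uptake = 0), strategy_spec("usual_care"),
                   const_life_table(0), flat_payoffs(utility = 1),
                   discount_rate = 0)
  expect_equal(tr$discounted_qaly, 5.0)
  expect_equal(tr$discounted_cost, 0)
  expect_true(all(tr$occupancy[, "dead"] == 0))
})

test_that("the two-cycle hand-computed chain gives 0.475 QALYs", {
  # constant per-cycle death probability 0.1 <=> annual 1 - 0.9^4
  lt <- const_life_table(1 - 0.9^4)
  tr <- run_cohort(cohort_spec(uptake = 0), strategy_spec("usual_care"),
                   lt, flat_payoffs(utility = 1),
                   n_cycles = 2, discount_rate = 0)
  expect_equal(unname(tr$occupancy[, "usual_care"]), c(1.0, 0.9),
               tolerance = 1e-12)
  expect_equal(tr$discounted_qaly, 0.25 * (1 + 0.9), tolerance = 1e-12)
})

test_that("occupancy rows sum to one, dead is absorbing and non-decreasing", {
  lt <- synth_life_table()
  pay <- synth_trial_payoffs(seed = 2)$payoffs
  for (s in c("usual_care", "bs", "bs_extended")) {
    tr <- run_cohort(cohort_spec(), strategy_spec(s), lt, pay)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-12))
    expect_true(all(diff(tr$occupancy[, "dead"]) >= 0))
  }
})

test_that("effect states empty on schedule: one cycle for the service, two
           under extended effects", {
  lt <- const_life_table(0)
  pay <- ce_payoffs(2000, 0.7, 1200, 0.76)
  bs <- run_cohort(cohort_spec(uptake = 0.85), strategy_spec("bs"), lt, pay)
  expect_equal(unname(bs$occupancy[1, "bs_effect"]), 0.85)
  expect_equal(unname(bs$occupancy[2, "bs_effect"]), 0)
  expect_equal(unname(bs$occupancy[2, "no_change"]), 0.85)
  ext <- run_cohort(cohort_spec(uptake = 0.85), strategy_spec("bs_extended"),
                    lt, pay)
  expect_equal(unname(ext$occupancy[2, "bs_extended_effect"]), 0.85)
  expect_equal(unname(ext$occupancy[3, "no_change"]), 0.85)
  expect_equal(unname(ext$occupancy[3, "bs_extended_effect"]), 0)
})

test_that("zero uptake collapses the intervention onto usual care", {
  lt <- synth_life_table()
  pay <- synth_trial_payoffs(seed = 3)$payoffs
  uc <- run_cohort(cohort_spec(uptake = 0), strategy_spec("usual_care"),
                   lt, pay)
  bs <- run_cohort(cohort_spec(uptake = 0), strategy_spec("bs"), lt, pay)
  expect_equal(bs$occupancy, uc$occupancy, tolerance = 1e-15)
  expect_equal(bs$discounted_cost, uc$discounted_cost)
  expect_equal(bs$discounted_qaly, uc$discounted_qaly)
})

test_that("discounted totals are below undiscounted ones, equal only at
           rate zero", {
  lt <- synth_life_table()
  pay <- ce_payoffs(2000, 0.7)
  t0 <- run_cohort(cohort_spec(), strategy_spec("usual_care"), lt, pay,
                   discount_rate = 0)
  t35 <- run_cohort(cohort_spec(), strategy_spec("usual_care"), lt, pay)
  expect_lt(t35$discounted_cost, t0$discounted_cost)
  expect_lt(t35$discounted_qaly, t0$discounted_qaly)
})

test_that("raising a live-state utility or the uptake moves totals
           monotonically", {
  lt <- synth_life_table()
  base <- run_cohort(cohort_spec(), strategy_spec("bs"), lt,
                     ce_payoffs(2000, 0.70, 1200, 0.76))
  higher <- run_cohort(cohort_spec(), strategy_spec("bs"), lt,
                       ce_payoffs(2000, 0.70, 1200, 0.80))
  expect_gt(higher$discounted_qaly, base$discounted_qaly)

  qalys <- vapply(c(0, 0.4, 0.85, 1), function(u)
    run_cohort(cohort_spec(uptake = u), strategy_spec("bs"), lt,
               ce_payoffs(2000, 0.70, 1200, 0.76))$discounted_qaly,
    numeric(1))
  expect_true(all(diff(qalys) > 0))
})

test_that("extended effects accumulate at least the savings of the one-cycle
           service", {
  lt <- synth_life_table()
  pay <- ce_payoffs(2000, 0.70, 1200, 0.76)
  uc <- run_cohort(cohort_spec(), strategy_spec("usual_care"), lt, pay)
  bs <- run_cohort(cohort_spec(), strategy_spec("bs"), lt, pay)
  ext <- run_cohort(cohort_spec(), strategy_spec("bs_extended"), lt, pay)
  save_bs <- uc$discounted_cost - bs$discounted_cost
  save_ext <- uc$discounted_cost - ext$discounted_cost
  expect_gte(save_ext, save_bs)
  expect_gt(save_bs, 0)
})

test_that("a life table not covering the horizon is rejected", {
  lt <- const_life_table(0.1, ages = 75:76)
  expect_error(run_cohort(cohort_spec(), strategy_spec("usual_care"), lt,
                          flat_payoffs()), "no row for age 77")
})

test_that("incremental results follow the ICER definition with dominance
           and degeneracy flags", {
  lt <- synth_life_table()
  pay <- ce_payoffs(2000, 0.70, 1200, 0.76)
  uc <- run_cohort(cohort_spec(), strategy_spec("usual_care"), lt, pay)
  bs <- run_cohort(cohort_spec(), strategy_spec("bs"), lt, pay)
  res <- incremental_results(uc, bs)
  expect_equal(res$icer, res$delta_cost / res$delta_qaly)
  expect_identical(res$status, "dominant")

  # the printed rounded base case: -663 / 0.013 = -51,000
  expect_equal(-663 / 0.013, -51000, tolerance = 1e-12)

  same <- incremental_results(uc, uc)
  expect_identical(same$status, "equivalent")
  expect_true(is.na(same$icer))
  expect_equal(same$delta_cost, 0)

  # zero QALY difference with a cost difference: undefined, never infinite
  cheap <- run_cohort(cohort_spec(), strategy_spec("bs"), lt,
                      ce_payoffs(2000, 0.70, 1200, 0.70))
  und <- incremental_results(uc, cheap)
  expect_identical(und$status, "undefined")
  expect_true(is.na(und$icer))
})

test_that("delta-method intervals: zero-width at zero variance, exact for
           linear maps, agreeing with Monte Carlo", {
  ci0 <- delta_ci(5, c(1, 2), c(0, 0))
  expect_equal(unname(ci0), c(5, 5))
  ci <- delta_ci(0, 3, 4)  # slope 3, sd 2
  expect_equal(unname(ci[2] - ci[1]) / 2, stats::qnorm(0.975) * 6)
  expect_error(delta_ci(0, 1, Inf), "non-finite")
  expect_error(delta_ci(0, 1, -1), "negative")

  # Monte Carlo agreement for a linear combination
  set.seed(7)
  g <- c(2, -1); v <- c(0.5, 1.2)
  draws <- g[1] * stats::rnorm(4000, 0, sqrt(v[1])) +
    g[2] * stats::rnorm(4000, 0, sqrt(v[2]))
  mc_hw <- diff(stats::quantile(draws, c(0.025, 0.975))) / 2
  dm_hw <- diff(delta_ci(0, g, v)) / 2
  expect_lt(abs(dm_hw - mc_hw) / mc_hw, 0.1)
})

test_that("delta-method CE intervals match a Monte Carlo interval through the
           full model", {
  lt <- synth_life_table()
  sp <- synth_trial_payoffs(seed = 11)
  uc <- run_cohort(cohort_spec(), strategy_spec("usual_care"), lt,
                   sp$payoffs)
  bs <- run_cohort(cohort_spec(), strategy_spec("bs"), lt, sp$payoffs)
  res <- incremental_results(uc, bs)
  ps <- draw_psa(cohort_spec(), lt, sp$payoffs, n = 1000, seed = 13)
  mc_cost <- stats::quantile(ps$draws$delta_cost, c(0.025, 0.975))
  mc_qaly <- stats::quantile(ps$draws$delta_qaly, c(0.025, 0.975))
  expect_lt(abs(diff(res$ci95_cost) - diff(mc_cost)) / diff(mc_cost), 0.10)
  expect_lt(abs(diff(res$ci95_qaly) - diff(mc_qaly)) / diff(mc_qaly), 0.10)
})
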