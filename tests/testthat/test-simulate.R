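test_that("generators are bit-reproducible under a fixed seed", {
  d <- default_attributes()
  a <- simulate_choice_data(d, n_respondents = 30, seed = 3)
  b <- simulate_choice_data(d, n_respondents = 30, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))

  p1 <- synth_trial_payoffs(seed = 5)
  p2 <- synth_trial_payoffs(seed = 5)
  expect_identical(p1$payoffs$params, p2$payoffs$params)

  expect_identical(synth_life_table(), synth_life_table())
})

test_that("a truth whose coefficients miss the design is rejected", {
  d <- tiny_design()
  bad <- coefficient_set(asc = 1, betas = c("place:castle" = 1), design = d)
  expect_error(simulate_choice_data(d, truth = bad, n_respondents = 5),
               "matches no design level")
})

test_that("a dominant any-service constant leaves the opt-out almost never
           chosen", {
  d <- tiny_design()
  truth <- coefficient_set(asc = 10, betas = c("place:home_visit" = 0),
                           design = d)
  dat <- simulate_choice_data(d, truth, n_respondents = 300, n_tasks = 6,
                              seed = 9)
  share_opt <- mean(dat$chosen[dat$is_opt_out == 1])
  expect_lt(share_opt, 0.01)
})

test_that("a zero truth chooses each alternative a third of the time", {
  d <- tiny_design()
  truth <- coefficient_set(asc = 0, betas = c("place:home_visit" = 0),
                           design = d)
  dat <- simulate_choice_data(d, truth, n_respondents = 1700, n_tasks = 6,
                              seed = 15)
  shares <- tapply(dat$chosen, dat$alt_id, mean)
  expect_true(all(abs(shares - 1 / 3) < 0.02))
})

test_that("empirical choice shares converge to the softmax probabilities", {
  # one fixed task repeated 5000 times
  d <- tiny_design()
  truth <- coefficient_set(asc = 1.0,
                           betas = c("place:home_visit" = 0.4,
                                     "review:comprehensive" = 0.2),
                           design = d)
  n <- 5000
  a <- data.frame(respondent_id = 1:n, task_id = 1, alt_id = 1,
                  chosen = NA_real_, is_opt_out = 0L,
                  place = "home_visit", review = "comprehensive")
  b <- transform(a, alt_id = 2, place = "gp_surgery",
                 review = "non_medicinal_only")
  o <- transform(a, alt_id = 3, is_opt_out = 1L, place = NA_character_,
                 review = NA_character_)
  dat <- choice_data(rbind(a, b, o), d)
  u <- c(1.0 + 0.4 + 0.2, 1.0, 0)
  p_true <- exp(u) / sum(exp(u))

  set.seed(27)
  g <- -log(-log(stats::runif(3 * n)))
  df <- as.data.frame(dat)
  util_row <- ifelse(df$is_opt_out == 1, 0,
                     ifelse(df$alt_id == 1, u[1], u[2]))
  key <- paste(df$respondent_id, df$task_id)
  tot <- util_row + g
  df$chosen <- as.numeric(tot == stats::ave(tot, key, FUN = max))
  shares <- tapply(df$chosen, df$alt_id, mean)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(shares - p_true) < 3 * se + 1e-12))

  # the package generator on random tasks agrees with per-task softmax in
  # aggregate: chosen utilities should average higher than uniform
  sim <- simulate_choice_data(d, truth, n_respondents = 900, n_tasks = 6,
                              seed = 33)
  expect_lt(mean(sim$chosen[sim$is_opt_out == 1]), 0.35)
})

test_that("trial payoff generator recovers its configured moments", {
  sp <- synth_trial_payoffs(n_per_arm = 100, seed = 19)
  tr <- sp$truth
  # configured mean cost within 3 standard errors
  se_cost <- sqrt(sp$arms$control$cost_var)
  expect_lt(abs(sp$arms$control$cost_mean - tr$cost_means[["control"]]),
            3 * se_cost)
  se_eff <- sqrt(sp$arms$effect$cost_var)
  expect_lt(abs(sp$arms$effect$cost_mean - tr$cost_means[["effect"]]),
            3 * se_eff)

  # null effect sizes: arm difference within 3 SEs of zero
  null_sp <- synth_trial_payoffs(effect_cost_change = 0,
                                 effect_utility_gain = 0, seed = 21)
  dd <- null_sp$arms$effect$cost_mean - null_sp$arms$control$cost_mean
  se_dd <- sqrt(null_sp$arms$effect$cost_var +
                  null_sp$arms$control$cost_var)
  expect_lt(abs(dd), 3 * se_dd)

  # utilities respect the EQ-5D bounds
  tight <- synth_trial_payoffs(control_utility_mean = 0.9,
                               effect_utility_gain = 0.05,
                               utility_sd = 0.3, seed = 25)
  expect_true(tight$payoffs$params$mean[3] <= 1)
  expect_gt(tight$n_resampled, 0)
})

test_that("life-table generator: limits, growth and clamping", {
  zero <- synth_life_table(base_annual_mortality = 0)
  expect_true(all(zero$annual_all_cause == 0))
  flat <- synth_life_table(gompertz_slope = 0)
  expect_equal(length(unique(round(
    flat$annual_all_cause[flat$sex == "male"], 12))), 1L)

  # base 0.04 at 75 with slope log(1.1): p(76) = 0.044
  lt <- synth_life_table(base_annual_mortality = 0.04)
  p75 <- lt$annual_all_cause[lt$age == 75 & lt$sex == "male"]
  p76 <- lt$annual_all_cause[lt$age == 76 & lt$sex == "male"]
  expect_equal(p75, 0.04)
  expect_equal(p76 / p75, 1.1, tolerance = 1e-12)

  expect_warning(synth_life_table(ages = 65:120), "clamped")
  clamped <- suppressWarnings(synth_life_table(ages = 65:120))
  expect_true(all(clamped$annual_all_cause <= 1))

  # respiratory mortality is the configured fraction of all-cause
  expect_equal(lt$annual_respiratory, 0.35 * lt$annual_all_cause)
})

test_that("full-loop recovery: simulated preferences refit to the true
           uptake probability", {
  d <- default_attributes()
  truth <- synthetic_truth(d)
  dat <- simulate_choice_data(d, truth, n_respondents = 500, n_tasks = 6,
                              seed = 37)
  fit <- fit_conditional_logit(dat)
  for (cfg in list(ref_config(),
                   service_config(place = "outpatient_clinic",
                                  review = "comprehensive",
                                  support = "therapists_and_social_worker",
                                  waiting = "2_weeks"))) {
    p_true <- uptake_probability(truth, cfg)$probability
    p_hat <- uptake_probability(fit$coefficients, cfg)$probability
    expect_lt(abs(p_hat - p_true), 0.03)
  }
})

test_that("sidecar truth files capture coefficients, payoffs and seed", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  truth <- synthetic_truth()
  sp <- synth_trial_payoffs(seed = 43)
  write_synthetic_truth(tmp, truth = truth, payoff_truth = sp$truth,
                        seed = 43)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$true_coefficients$asc, 1.52)
  expect_equal(back$payoff_truth$effect_cost_change, -780)
  expect_equal(back$seed, 43)
})
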