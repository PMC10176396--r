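test_that("log-likelihood matches literal softmax enumeration on small
           datasets", {
  d <- default_attributes()
  set.seed(31)
  for (n_tasks in c(1, 3, 5)) {
    dat <- simulate_choice_data(d, n_respondents = 1, n_tasks = n_tasks,
                                seed = sample.int(1e6, 1))
    p <- ncol(build_design_matrix(dat))
    for (r in 1:3) {
      beta <- stats::rnorm(p, sd = 0.8)
      expect_equal(clogit_loglik(beta, dat),
                   brute_force_loglik(beta, dat), tolerance = 1e-10)
    }
  }
})

test_that("closed-form values: uniform choice and a single known task", {
  d <- default_attributes()
  dat <- simulate_choice_data(d, n_respondents = 7, n_tasks = 6, seed = 4)
  p <- ncol(build_design_matrix(dat))
  # beta = 0: every alternative equally likely -> -T log 3
  expect_equal(clogit_loglik(numeric(p), dat), -42 * log(3))

  # one task with utilities (asc, 0, 0) and the service chosen:
  # log(e^asc / (e^asc + 2)); asc = 1 gives log(e / (e + 2))
  one <- as.data.frame(simulate_choice_data(d, n_respondents = 1, n_tasks = 1, seed = 8))
  one$chosen <- c(1, 0, 0)[order(c(1, 2, 3))]
  one$chosen <- ifelse(one$alt_id == 1, 1, 0)
  dat1 <- choice_data(one, d)
  beta <- numeric(p)
  beta[1] <- 1  # asc only: both services have utility 1, opt-out 0
  expect_equal(clogit_loglik(beta, dat1), log(exp(1) / (2 * exp(1) + 1)))
})

test_that("likelihood and fit are invariant to alternative order within
           tasks", {
  d <- default_attributes()
  dat <- simulate_choice_data(d, n_respondents = 40, n_tasks = 6, seed = 13)
  df <- as.data.frame(dat)
  set.seed(99)
  perm <- unlist(tapply(seq_len(nrow(df)),
                        interaction(df$respondent_id, df$task_id,
                                    drop = TRUE),
                        sample))
  df2 <- df[perm, ]
  df2$alt_id <- stats::ave(df2$alt_id, df2$respondent_id, df2$task_id,
                           FUN = seq_along)
  dat2 <- choice_data(df2, d)
  p <- ncol(build_design_matrix(dat))
  beta <- stats::rnorm(p, sd = 0.5)
  expect_equal(clogit_loglik(beta, dat2), clogit_loglik(beta, dat))
  f1 <- fit_conditional_logit(dat)
  f2 <- fit_conditional_logit(dat2)
  expect_equal(f1$coefficients$betas, f2$coefficients$betas,
               tolerance = 1e-8)
})

test_that("dimension mismatch and unanswered-task handling", {
  d <- default_attributes()
  dat <- simulate_choice_data(d, n_respondents = 5, n_tasks = 6, seed = 3)
  expect_error(clogit_loglik(c(0, 0), dat), "columns")
  df <- as.data.frame(dat)
  df$chosen[df$respondent_id == 1 & df$task_id == 1] <- NA
  dat_na <- choice_data(df, d)
  p <- ncol(build_design_matrix(dat))
  expect_equal(clogit_loglik(numeric(p), dat_na), -29 * log(3))
})

test_that("the fit agrees with an independent conditional logit
           implementation", {
  skip_if_not_installed("survival")
  d <- default_attributes()
  dat <- simulate_choice_data(d, n_respondents = 120, n_tasks = 6, seed = 21)
  fit <- fit_conditional_logit(dat, cluster_se = FALSE)
  X <- build_design_matrix(dat)
  strat <- as.integer(interaction(dat$respondent_id, dat$task_id,
                                  drop = TRUE))
  suppressPackageStartupMessages(library(survival))
  sv <- clogit(dat$chosen ~ X + strata(strat))
  expect_equal(unname(c(fit$coefficients$asc, fit$coefficients$betas)),
               unname(coef(sv)), tolerance = 1e-5)
  expect_equal(fit$log_likelihood, as.numeric(logLik(sv)),
               tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov_model))),
               unname(sqrt(diag(vcov(sv)))), tolerance = 1e-4)
})

test_that("optimisation reaches the same optimum from dispersed starts
           (concavity)", {
  d <- default_attributes()
  dat <- simulate_choice_data(d, n_respondents = 60, n_tasks = 6, seed = 17)
  p <- ncol(build_design_matrix(dat))
  set.seed(42)
  fits <- lapply(1:5, function(i)
    fit_conditional_logit(dat, start = stats::rnorm(p, sd = 1.5)))
  ref <- c(fits[[1]]$coefficients$asc, fits[[1]]$coefficients$betas)
  for (f in fits[-1]) {
    expect_true(f$converged)
    expect_equal(c(f$coefficients$asc, f$coefficients$betas), ref,
                 tolerance = 1e-6)
  }
})

test_that("a null truth yields estimates within 3 standard errors of zero", {
  d <- default_attributes()
  null_truth <- coefficient_set(asc = 0, betas = c("place:home_visit" = 0),
                                design = d)
  dat <- simulate_choice_data(d, n_respondents = 200, n_tasks = 6,
                              truth = null_truth, seed = 55)
  fit <- fit_conditional_logit(dat, cluster_se = FALSE)
  est <- c(fit$coefficients$asc, fit$coefficients$betas)
  se <- sqrt(diag(fit$vcov_model))
  expect_true(all(abs(est) < 3 * se))
})

test_that("likelihood-ratio test: identical fits give statistic 0, inverted
           nesting is rejected, and the null chi-square calibrates", {
  d <- default_attributes()
  dat <- simulate_choice_data(d, n_respondents = 50, n_tasks = 6, seed = 29)
  fit <- fit_conditional_logit(dat)
  same <- lr_test(fit, fit)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$df, 0L)
  expect_error(lr_test(-100, -90, df = 2), "below the nested")

  # small chi-square calibration: patients-vs-carers style split under a
  # shared truth; statistic ~ chi-square(df = parameters)
  set.seed(61)
  stats_null <- replicate(60, {
    dat <- simulate_choice_data(d, n_respondents = 60, n_tasks = 6,
                                seed = sample.int(1e6, 1))
    df <- as.data.frame(dat)
    g1 <- choice_data(df[df$respondent_id <= 30, ], d)
    g2 <- choice_data(df[df$respondent_id > 30, ], d)
    full <- list(fit_conditional_logit(g1), fit_conditional_logit(g2))
    nested <- fit_conditional_logit(dat)
    lr_test(full, nested)$statistic
  })
  df_expected <- 1 + length(fit$coefficients$betas)
  expect_gt(mean(stats_null), df_expected - 2.5)
  expect_lt(mean(stats_null), df_expected + 2.5)
})

test_that("cluster bootstrap is seeded and degenerates correctly", {
  d <- default_attributes()
  dat <- simulate_choice_data(d, n_respondents = 40, n_tasks = 6, seed = 71)
  const <- cluster_bootstrap(dat, function(cs) 1.0, n_boot = 100, seed = 1)
  expect_equal(unname(const$ci[1, "low"]), 1.0)
  expect_equal(unname(const$ci[1, "high"]), 1.0)

  b1 <- cluster_bootstrap(dat, function(cs) cs$asc, n_boot = 100, seed = 9)
  b2 <- cluster_bootstrap(dat, function(cs) cs$asc, n_boot = 100, seed = 9)
  expect_identical(b1$ci, b2$ci)
  expect_lt(b1$ci[1, "low"], b1$ci[1, "high"])
  expect_error(cluster_bootstrap(dat, function(cs) cs$asc, n_boot = 10),
               "at least 100")
})

test_that("separation-prone data is flagged rather than silently returned", {
  # deterministic choices: the home-visit alternative is always taken
  d <- tiny_design()
  truth <- coefficient_set(asc = 30,
                           betas = c("place:home_visit" = 30,
                                     "place:outpatient_clinic" = -30,
                                     "review:comprehensive" = 0),
                           design = d)
  dat <- simulate_choice_data(d, n_respondents = 30, n_tasks = 6,
                              truth = truth, seed = 101)
  expect_warning(fit_conditional_logit(dat, max_iter = 60), "separation")
})
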