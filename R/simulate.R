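#' Default synthetic preference truth
#'
#' A coefficient set for the default attribute catalogue, usable as the
#' generating truth for simulated choice data. The any-service constant and
#' the place, review and support coefficients take the published point
#' estimates for this service type (ASC 1.52; GP surgery -0.30; outpatient
#' clinic 0.16; home visit 0.15; comprehensive review 0.15; holistic
#' therapist-plus-social-worker support 0.19; no additional support -0.23;
#' social worker alone -0.15). The waiting-time coefficients were never
#' published and are synthetic placeholders (2 weeks +0.25, 4 weeks +0.10,
#' 8 weeks reference 0) chosen to make shorter waits preferred. Note the
#' place and support entries assign a value to every level (as published),
#' not contrasts against a reference; utilities are simply the sum of the
#' configuration's entries plus the constant.
#'
#' @param design Attribute catalogue (default [default_attributes()]).
#' @return A [coefficient_set()] without covariance.
#' @export
synthetic_truth <- function(design = default_attributes()) {
  coefficient_set(
    asc = 1.52,
    betas = c("place:gp_surgery" = -0.30,
              "place:outpatient_clinic" = 0.16,
              "place:home_visit" = 0.15,
              "review:comprehensive" = 0.15,
              "support:therapists_and_social_worker" = 0.19,
              "support:none" = -0.23,
              "support:social_worker_only" = -0.15,
              "waiting:2_weeks" = 0.25,     # synthetic placeholder
              "waiting:4_weeks" = 0.10),    # synthetic placeholder
    design = design)
}

# fitted-scale truth implied by a per-level truth: the dummy-coded ASC
# absorbs the reference-level contributions
implied_asc <- function(truth) {
  out <- truth$asc
  for (a in truth$design) {
    k <- paste0(a$name, ":", a$reference)
    if (k %in% names(truth$betas)) out <- out + truth$betas[[k]]
  }
  out
}

# contrasts implied by a per-level truth, in design-matrix column order:
# beta_col = truth(level) - truth(reference)
implied_contrasts <- function(truth) {
  out <- numeric(0)
  for (a in truth$design) {
    val <- function(l) {
      k <- paste0(a$name, ":", l)
      if (k %in% names(truth$betas)) truth$betas[[k]] else 0
    }
    for (l in setdiff(a$levels, a$reference))
      out[paste0(a$name, ":", l)] <- val(l) - val(a$reference)
  }
  out
}

#' Simulate choice responses from a known utility vector
#'
#' Generates random paired tasks with [generate_choice_tasks()] and draws
#' each response from the softmax over the three alternatives' utilities
#' (the two services' utilities from `truth`, the opt-out at 0), via the
#' equivalent Gumbel-error maximisation. Bit-reproducible under a fixed
#' seed.
#'
#' @param design Attribute catalogue.
#' @param truth A [coefficient_set()] covering the design.
#' @param n_respondents,n_tasks Study geometry (defaults 256 x 6, the study
#'   format).
#' @param seed Optional integer seed.
#' @return A `choice_data` object with `chosen` filled in.
#' @export
simulate_choice_data <- function(design = default_attributes(),
                                 truth = synthetic_truth(design),
                                 n_respondents = 256, n_tasks = 6,
                                 seed = NULL) {
  nm <- design_names(design)
  for (k in names(truth$betas)) {
    if (grepl(":", k, fixed = TRUE)) {
      parts <- strsplit(k, ":", fixed = TRUE)[[1]]
      a <- which(nm == parts[1])
      if (!length(a) || !parts[2] %in% design[[a]]$levels)
        stop("truth coefficient '", k, "' matches no design level",
             call. = FALSE)
    } else if (!k %in% nm) {
      stop("truth coefficient '", k, "' matches no design attribute",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  data <- generate_choice_tasks(design, n_respondents, n_tasks, seed = NULL)
  u <- row_utilities(truth, data)
  g <- -log(-log(stats::runif(nrow(data))))          # Gumbel(0, 1) errors
  key <- interaction(data$respondent_id, data$task_id, drop = TRUE)
  total <- u + g
  winner <- stats::ave(total, key, FUN = max)
  data$chosen <- as.numeric(total == winner)
  choice_data(as.data.frame(data), design)
}

# vectorised per-row utilities under a coefficient set (opt-out rows 0)
row_utilities <- function(coeffs, data) {
  design <- attr(data, "design")
  svc <- data$is_opt_out == 0L
  u <- ifelse(svc, coeffs$asc, 0)
  for (a in design) {
    lv <- data[[a$name]]
    if (a$coding == "linear") {
      contrib <- coeffs$betas[[a$name]] *
        (a$values[lv] - a$values[[a$reference]])
    } else {
      lookup <- stats::setNames(numeric(length(a$levels)), a$levels)
      keys <- paste0(a$name, ":", a$levels)
      hit <- keys %in% names(coeffs$betas)
      lookup[a$levels[hit]] <- coeffs$betas[keys[hit]]
      contrib <- lookup[lv]
    }
    contrib[!svc | is.na(lv)] <- 0
    u <- u + as.numeric(contrib)
  }
  u
}

#' Simulate trial-like per-cycle payoffs
#'
#' Emulates a two-arm trial measuring per-patient cycle costs (gamma
#' distributed) and EQ-5D utilities (normal, resampled into the configured
#' bounds) for a usual-care arm and an intervention arm whose effect period
#' changes costs by `effect_cost_change` and utility by
#' `effect_utility_gain`. Returns arm-level means and variances of the
#' means, packaged as the payoff inputs of the cohort model.
#'
#' @param n_per_arm Patients per arm (default 100).
#' @param control_cost_mean Mean cycle cost under usual care (GBP, default
#'   2000).
#' @param control_utility_mean Mean EQ-5D under usual care (default 0.70).
#' @param effect_cost_change Additive cost change during the effect period
#'   (default -780 GBP per cycle).
#' @param effect_utility_gain Additive utility change during the effect
#'   period (default +0.06).
#' @param cost_cv Coefficient of variation of per-patient costs (default
#'   0.5).
#' @param utility_sd Per-patient utility standard deviation (default 0.15).
#' @param utility_bounds EQ-5D bounds for resampling (default c(-0.6, 1)).
#' @param seed Optional integer seed.
#' @return A `synth_payoffs` list: `payoffs` (a [ce_payoffs()]), `arms`
#'   (per-arm summaries), `truth` (the configured generating values),
#'   `n_resampled`, `seed`.
#' @export
synth_trial_payoffs <- function(n_per_arm = 100,
                                control_cost_mean = 2000,
                                control_utility_mean = 0.70,
                                effect_cost_change = -780,
                                effect_utility_gain = 0.06,
                                cost_cv = 0.5, utility_sd = 0.15,
                                utility_bounds = c(-0.6, 1),
                                seed = NULL) {
  stopifnot(n_per_arm >= 2, control_cost_mean > 0,
            is.finite(effect_cost_change), is.finite(effect_utility_gain))
  mu_cost <- c(control = control_cost_mean,
               effect = control_cost_mean + effect_cost_change)
  mu_util <- c(control = control_utility_mean,
               effect = control_utility_mean + effect_utility_gain)
  if (any(mu_cost < 0)) stop("configured mean cost is negative",
                             call. = FALSE)
  if (any(mu_util < utility_bounds[1] | mu_util > utility_bounds[2]))
    stop("configured mean utility outside the EQ-5D bounds", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_resampled <- 0L
  draw_arm <- function(arm) {
    shape <- 1 / cost_cv^2
    costs <- stats::rgamma(n_per_arm, shape = shape,
                           rate = shape / mu_cost[[arm]])
    utils <- stats::rnorm(n_per_arm, mu_util[[arm]], utility_sd)
    bad <- utils < utility_bounds[1] | utils > utility_bounds[2]
    while (any(bad)) {
      n_resampled <<- n_resampled + sum(bad)
      utils[bad] <- stats::rnorm(sum(bad), mu_util[[arm]], utility_sd)
      bad <- utils < utility_bounds[1] | utils > utility_bounds[2]
    }
    list(cost_mean = mean(costs), cost_var = stats::var(costs) / n_per_arm,
         utility_mean = mean(utils),
         utility_var = stats::var(utils) / n_per_arm, n = n_per_arm)
  }
  ctl <- draw_arm("control")
  eff <- draw_arm("effect")
  payoffs <- ce_payoffs(
    control_cost = ctl$cost_mean, control_utility = ctl$utility_mean,
    effect_cost = eff$cost_mean, effect_utility = eff$utility_mean,
    control_cost_var = ctl$cost_var, control_utility_var = ctl$utility_var,
    effect_cost_var = eff$cost_var, effect_utility_var = eff$utility_var)
  structure(list(payoffs = payoffs, arms = list(control = ctl, effect = eff),
                 truth = list(cost_means = mu_cost, utility_means = mu_util,
                              effect_cost_change = effect_cost_change,
                              effect_utility_gain = effect_utility_gain,
                              cost_cv = cost_cv, utility_sd = utility_sd,
                              n_per_arm = n_per_arm),
                 n_resampled = n_resampled, seed = seed),
            class = "synth_payoffs")
}

#' Generate a synthetic life table
#'
#' Gompertz-type growth: annual all-cause mortality equals
#' `base_annual_mortality * exp(gompertz_slope * (age - anchor_age))`,
#' scaled per sex, clamped to `[0, 1]` (with a warning naming the first
#' affected age); respiratory mortality is a fixed fraction of all-cause.
#' Purely synthetic — a stand-in for a published national life table.
#'
#' @param ages Integer ages to tabulate (default 65:95).
#' @param sexes Sexes to tabulate.
#' @param base_annual_mortality All-cause annual probability at
#'   `anchor_age` for the first sex (default 0.08).
#' @param respiratory_fraction Respiratory share of all-cause mortality
#'   (default 0.35).
#' @param gompertz_slope Log-linear growth per year of age (default
#'   `log(1.1)`, a ~10%/year increase).
#' @param anchor_age Age at which the base applies (default 75).
#' @param sex_factors Named multipliers per sex.
#' @return Life-table data frame (`age`, `sex`, `annual_all_cause`,
#'   `annual_respiratory`).
#' @export
synth_life_table <- function(ages = 65:95, sexes = c("male", "female"),
                             base_annual_mortality = 0.08,
                             respiratory_fraction = 0.35,
                             gompertz_slope = log(1.1),
                             anchor_age = 75,
                             sex_factors = c(male = 1, female = 0.8)) {
  stopifnot(base_annual_mortality >= 0, base_annual_mortality <= 1,
            respiratory_fraction >= 0, respiratory_fraction <= 1)
  out <- expand.grid(age = ages, sex = sexes, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  fac <- sex_factors[out$sex]
  raw <- base_annual_mortality * fac *
    exp(gompertz_slope * (out$age - anchor_age))
  if (any(raw > 1))
    warning("mortality clamped to 1 from age ",
            min(out$age[raw > 1]), call. = FALSE)
  out$annual_all_cause <- pmin(1, pmax(0, raw))
  out$annual_respiratory <- respiratory_fraction * out$annual_all_cause
  out[order(out$sex, out$age), c("age", "sex", "annual_all_cause",
                                 "annual_respiratory")]
}

#' Write the generating truth of a synthetic dataset as a sidecar JSON
#'
#' Records everything needed for recovery testing next to a generated
#' dataset: the true coefficient set, any payoff truth, and the seed.
#'
#' @param path Output JSON path.
#' @param truth Optional [coefficient_set()].
#' @param payoff_truth Optional `truth` element of a [synth_trial_payoffs()]
#'   result.
#' @param seed Seed used for generation.
#' @export
write_synthetic_truth <- function(path, truth = NULL, payoff_truth = NULL,
                                  seed = NULL) {
  out <- list(seed = seed)
  if (!is.null(truth))
    out$true_coefficients <- list(asc = truth$asc,
                                  betas = as.list(truth$betas))
  if (!is.null(payoff_truth)) out$payoff_truth <- payoff_truth
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
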