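#' States of the Markov cohort model
#'
#' Mutually exclusive health/service states: receiving usual care only;
#' benefiting from the breathlessness service (first effect cycle); still
#' benefiting under the extended-effect scenario (second effect cycle); back
#' on usual-care payoffs after the service effect has worn off
#' (`no_change`); and the absorbing `dead` state.
#'
#' @export
markov_states <- function() {
  c("usual_care", "bs_effect", "bs_extended_effect", "no_change", "dead")
}

#' Per-cycle discount factor
#'
#' Compound discounting at an annual rate over 12-week (0.25-year) cycles:
#' `(1 + rate)^(-0.25 * cycle_index)`, so cycle 0 is undiscounted and four
#' cycles equal one year of discounting.
#'
#' @param cycle_index Non-negative cycle count (vectorised).
#' @param annual_rate Annual discount rate (default 3.5%).
#' @param cycle_length_years Cycle length in years (default 0.25).
#' @return Discount factor(s) in (0, 1].
#' @export
per_cycle_discount <- function(cycle_index, annual_rate = 0.035,
                               cycle_length_years = 0.25) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0", call. = FALSE)
  if (annual_rate < 0) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle_length_years * cycle_index)
}

#' Convert an annual death probability to a per-cycle probability
#'
#' Assumes a constant hazard within the year: `1 - (1 - p)^0.25` for a
#' quarter-year cycle.
#'
#' @param p_annual Annual probability in `[0, 1]` (vectorised).
#' @param cycle_length_years Cycle length in years (default 0.25).
#' @return Per-cycle probability.
#' @export
annual_to_cycle_probability <- function(p_annual, cycle_length_years = 0.25) {
  if (any(p_annual < 0 | p_annual > 1))
    stop("annual probability outside [0, 1]", call. = FALSE)
  1 - (1 - p_annual)^cycle_length_years
}

validate_life_table <- function(life_table) {
  life_table <- as.data.frame(life_table)
  need <- c("age", "sex", "annual_all_cause", "annual_respiratory")
  missing <- setdiff(need, names(life_table))
  if (length(missing))
    stop("life table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (cc in c("annual_all_cause", "annual_respiratory"))
    if (any(life_table[[cc]] < 0 | life_table[[cc]] > 1))
      stop("life-table column ", cc, " outside [0, 1]", call. = FALSE)
  life_table
}

lookup_mortality <- function(life_table, age, sex, column) {
  hit <- life_table$age == age & life_table$sex == sex
  if (!any(hit))
    stop("life table has no row for age ", age, ", sex '", sex, "'",
         call. = FALSE)
  life_table[[column]][which(hit)[1]]
}

#' Define the starting cohort
#'
#' @param age_start Age in years at model entry (default 75, the base case).
#' @param sex `"male"` or `"female"`.
#' @param diagnosis Free-text label (e.g. `"COPD"`).
#' @param uptake Probability that an offered service is taken up, from the
#'   preference model (base case 0.85).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(age_start = 75, sex = c("male", "female"),
                        diagnosis = "COPD", uptake = 0.85) {
  sex <- match.arg(sex)
  stopifnot(age_start > 0, uptake >= 0, uptake <= 1)
  structure(list(age_start = age_start, sex = sex, diagnosis = diagnosis,
                 uptake = uptake), class = "cohort_spec")
}

#' Define a strategy
#'
#' Three comparators: usual care only; the breathlessness service whose
#' effect wears off after the first 12-week cycle (`effect_cycles = 1`); and
#' the service with extended effects lasting a second cycle
#' (`effect_cycles = 2`). For intervention strategies the cohort splits at
#' entry: the uptake fraction starts in `bs_effect`, the remainder in
#' `usual_care`.
#'
#' @param name `"usual_care"`, `"bs"` or `"bs_extended"`.
#' @param effect_cycles Override for the number of effect cycles (0, 1, 2);
#'   defaults follow the name.
#' @return A `strategy_spec` object.
#' @export
strategy_spec <- function(name = c("usual_care", "bs", "bs_extended"),
                          effect_cycles = NULL) {
  name <- match.arg(name)
  if (is.null(effect_cycles))
    effect_cycles <- switch(name, usual_care = 0L, bs = 1L, bs_extended = 2L)
  if (!effect_cycles %in% 0:2)
    stop("effect_cycles must be 0, 1 or 2", call. = FALSE)
  structure(list(name = name, effect_cycles = as.integer(effect_cycles),
                 uptake_applied = name != "usual_care",
                 states = markov_states()),
            class = "strategy_spec")
}

#' Per-cycle payoffs by trial arm
#'
#' Cycle costs (GBP per 12-week cycle) and EQ-5D utilities are estimated per
#' trial arm, so states sharing an arm share one estimated parameter:
#' `usual_care` and `no_change` carry the control-arm payoffs, the two
#' effect states the intervention-arm payoffs. Variances are of the mean
#' estimates and drive delta-method intervals and the probabilistic
#' sensitivity analysis.
#'
#' @param control_cost,effect_cost Mean cycle cost per arm (>= 0).
#' @param control_utility,effect_utility Mean EQ-5D utility per arm (<= 1;
#'   negative health states allowed).
#' @param control_cost_var,effect_cost_var,control_utility_var,effect_utility_var
#'   Variances of those means (default 0 = known exactly).
#' @return A `ce_payoffs` object: `params` data frame (`param`, `quantity`,
#'   `mean`, `var`) and `state_map` linking each live state to its cost and
#'   utility parameter.
#' @export
ce_payoffs <- function(control_cost, control_utility,
                       effect_cost = control_cost,
                       effect_utility = control_utility,
                       control_cost_var = 0, control_utility_var = 0,
                       effect_cost_var = 0, effect_utility_var = 0) {
  if (min(control_cost, effect_cost) < 0)
    stop("cycle costs must be >= 0", call. = FALSE)
  if (max(control_utility, effect_utility) > 1)
    stop("EQ-5D utilities must be <= 1", call. = FALSE)
  if (min(control_cost_var, control_utility_var,
          effect_cost_var, effect_utility_var) < 0)
    stop("variances must be >= 0", call. = FALSE)
  params <- data.frame(
    param = c("cost_control", "cost_effect",
              "utility_control", "utility_effect"),
    quantity = c("cost", "cost", "utility", "utility"),
    mean = c(control_cost, effect_cost, control_utility, effect_utility),
    var = c(control_cost_var, effect_cost_var,
            control_utility_var, effect_utility_var),
    stringsAsFactors = FALSE)
  state_map <- data.frame(
    state = c("usual_care", "bs_effect", "bs_extended_effect", "no_change"),
    cost_param = c("cost_control", "cost_effect", "cost_effect",
                   "cost_control"),
    utility_param = c("utility_control", "utility_effect", "utility_effect",
                      "utility_control"),
    stringsAsFactors = FALSE)
  structure(list(params = params, state_map = state_map),
            class = "ce_payoffs")
}

payoff_means <- function(payoffs) {
  stats::setNames(payoffs$params$mean, payoffs$params$param)
}

# per-state cost / utility vectors (dead = 0) in markov_states() order
state_payoff_vectors <- function(payoffs, means = payoff_means(payoffs)) {
  st <- markov_states()
  cost <- utility <- stats::setNames(numeric(length(st)), st)
  m <- payoffs$state_map
  cost[m$state] <- means[m$cost_param]
  utility[m$state] <- means[m$utility_param]
  list(cost = cost, utility = utility)
}

#' Run the Markov cohort simulation
#'
#' Tracks start-of-cycle state occupancy over the horizon. Mortality uses
#' the all-cause schedule in the initial cycle(s) and the respiratory
#' schedule thereafter, both age- and sex-specific with age advanced every
#' four cycles; annual probabilities are converted to per-cycle ones by
#' [annual_to_cycle_probability()]. Costs and QALYs accrue on start-of-cycle
#' occupancy (no half-cycle correction) with compound per-cycle discounting;
#' each cycle contributes `utility x 0.25` life-years per occupant.
#'
#' @param cohort A [cohort_spec()].
#' @param strategy A [strategy_spec()].
#' @param life_table Data frame with columns `age`, `sex`,
#'   `annual_all_cause`, `annual_respiratory` covering the cohort's ages
#'   over the horizon.
#' @param payoffs A [ce_payoffs()] object.
#' @param n_cycles Horizon in cycles (default 20, i.e. 5 years).
#' @param discount_rate Annual discount rate (default 0.035).
#' @param cycle_length_years Cycle length (default 0.25).
#' @param all_cause_cycles Number of initial cycles using all-cause
#'   mortality before switching to respiratory mortality (default 1).
#' @return A `cohort_trace`: `occupancy` (cycles x states, start of cycle),
#'   `discounted_cost`, `discounted_qaly`, `cycle_costs`, `cycle_qalys`,
#'   and per-parameter accumulator weights (`weights`) such that total cost
#'   and QALY are linear in the payoff means.
#' @export
run_cohort <- function(cohort, strategy, life_table, payoffs,
                       n_cycles = 20, discount_rate = 0.035,
                       cycle_length_years = 0.25, all_cause_cycles = 1) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(strategy, "strategy_spec"),
            inherits(payoffs, "ce_payoffs"))
  life_table <- validate_life_table(life_table)
  st <- markov_states()
  pv <- state_payoff_vectors(payoffs)

  occ <- stats::setNames(numeric(length(st)), st)
  if (strategy$uptake_applied && strategy$effect_cycles > 0) {
    occ["bs_effect"] <- cohort$uptake
    occ["usual_care"] <- 1 - cohort$uptake
  } else if (strategy$uptake_applied) {
    # strategy offered but with no effect cycles: takers gain nothing
    occ["no_change"] <- cohort$uptake
    occ["usual_care"] <- 1 - cohort$uptake
  } else {
    occ["usual_care"] <- 1
  }

  occupancy <- matrix(0, n_cycles, length(st), dimnames = list(NULL, st))
  disc <- per_cycle_discount(seq_len(n_cycles) - 1, discount_rate,
                             cycle_length_years)
  # per-state discounted occupancy weights; totals are linear in payoffs
  w_state <- stats::setNames(numeric(length(st)), st)
  cycle_costs <- cycle_qalys <- numeric(n_cycles)

  for (t in seq_len(n_cycles)) {
    if (abs(sum(occ) - 1) > 1e-9)
      stop("internal consistency failure: occupancy drifted from 1",
           call. = FALSE)
    occupancy[t, ] <- occ
    w_state <- w_state + occ * disc[t]
    cycle_costs[t] <- sum(occ * pv$cost) * disc[t]
    cycle_qalys[t] <- sum(occ * pv$utility) * cycle_length_years * disc[t]

    age_t <- cohort$age_start + (t - 1) %/% 4
    column <- if (t <= all_cause_cycles) "annual_all_cause"
              else "annual_respiratory"
    p_cycle <- annual_to_cycle_probability(
      lookup_mortality(life_table, age_t, cohort$sex, column),
      cycle_length_years)

    nxt <- stats::setNames(numeric(length(st)), st)
    surv <- occ * (1 - p_cycle)
    nxt["dead"] <- occ[["dead"]] + sum(occ[st != "dead"]) * p_cycle
    nxt["usual_care"] <- surv[["usual_care"]]
    nxt["no_change"] <- surv[["no_change"]] + surv[["bs_extended_effect"]] +
      if (strategy$effect_cycles >= 2 && t < strategy$effect_cycles)
        0 else surv[["bs_effect"]]
    nxt["bs_extended_effect"] <-
      if (strategy$effect_cycles >= 2 && t < strategy$effect_cycles)
        surv[["bs_effect"]] else 0
    nxt["bs_effect"] <- 0
    occ <- nxt
  }

  sm <- payoffs$state_map
  w_cost <- tapply(w_state[sm$state], sm$cost_param, sum)
  w_util <- tapply(w_state[sm$state] * cycle_length_years, sm$utility_param,
                   sum)
  weights <- list(
    cost = stats::setNames(as.numeric(w_cost), names(w_cost)),
    qaly = stats::setNames(as.numeric(w_util), names(w_util)))

  structure(list(occupancy = occupancy,
                 discounted_cost = sum(cycle_costs),
                 discounted_qaly = sum(cycle_qalys),
                 cycle_costs = cycle_costs, cycle_qalys = cycle_qalys,
                 weights = weights,
                 cohort = cohort, strategy = strategy,
                 n_cycles = n_cycles, discount_rate = discount_rate,
                 cycle_length_years = cycle_length_years,
                 payoffs = payoffs),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("cohort trace [%s]: %d cycles, cost %.0f, QALY %.4f\n",
              x$strategy$name, x$n_cycles, x$discounted_cost,
              x$discounted_qaly))
  invisible(x)
}

#' Delta-method confidence interval
#'
#' First-order variance propagation: `var = g' V g` for a gradient `g` and
#' input covariance `V` (a vector of variances is treated as diagonal),
#' with a normal interval around the estimate. Exact for maps linear in the
#' inputs, which the trace accumulators are.
#'
#' @param estimate Point estimate.
#' @param gradient Numeric gradient vector.
#' @param variances Vector of input variances (independent inputs) or a
#'   covariance matrix.
#' @param level Interval coverage.
#' @return Named vector `c(low, high)`.
#' @export
delta_ci <- function(estimate, gradient, variances, level = 0.95) {
  if (any(!is.finite(unlist(variances))))
    stop("non-finite variance", call. = FALSE)
  v <- if (is.matrix(variances)) drop(gradient %*% variances %*% gradient)
       else {
         if (any(variances < 0)) stop("negative variance", call. = FALSE)
         sum(gradient^2 * variances)
       }
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = estimate - z * sqrt(v), high = estimate + z * sqrt(v))
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes the incremental cost, incremental QALY and their ratio
#' `ICER = delta_cost / delta_qaly`, with delta-method intervals propagated
#' from the payoff-parameter variances through the (linear) trace
#' accumulators of both arms. An intervention that costs less and yields
#' more QALYs is labelled `dominant`; less effect at more cost `dominated`;
#' both deltas zero `equivalent`; a zero QALY difference with a non-zero
#' cost difference leaves the ICER undefined and flagged rather than
#' infinite.
#'
#' @param control,intervention `cohort_trace` objects sharing cycle
#'   structure and payoff parameterisation.
#' @param level Interval coverage.
#' @return A `ce_result`: `delta_cost`, `delta_qaly`, their `ci95`s, `icer`
#'   (`NA` when undefined), `status` (`"icer"`, `"dominant"`, `"dominated"`,
#'   `"equivalent"`, `"undefined"`).
#' @export
incremental_results <- function(control, intervention, level = 0.95) {
  stopifnot(inherits(control, "cohort_trace"),
            inherits(intervention, "cohort_trace"))
  if (control$n_cycles != intervention$n_cycles ||
      control$cycle_length_years != intervention$cycle_length_years)
    stop("traces do not share a cycle structure", call. = FALSE)
  pay <- intervention$payoffs
  means <- payoff_means(pay)
  vars <- stats::setNames(pay$params$var, pay$params$param)

  g_cost <- intervention$weights$cost - control$weights$cost[
    names(intervention$weights$cost)]
  g_qaly <- intervention$weights$qaly - control$weights$qaly[
    names(intervention$weights$qaly)]
  dc <- intervention$discounted_cost - control$discounted_cost
  dq <- intervention$discounted_qaly - control$discounted_qaly

  ci_cost <- delta_ci(dc, g_cost, vars[names(g_cost)], level)
  ci_qaly <- delta_ci(dq, g_qaly, vars[names(g_qaly)], level)

  tol <- 1e-12
  if (abs(dq) < tol && abs(dc) < tol) {
    status <- "equivalent"; icer <- NA_real_
  } else if (abs(dq) < tol) {
    status <- "undefined"; icer <- NA_real_
  } else {
    icer <- dc / dq
    status <- if (dc < 0 && dq > 0) "dominant"
              else if (dc > 0 && dq < 0) "dominated" else "icer"
  }
  structure(list(delta_cost = dc, delta_qaly = dq,
                 ci95_cost = ci_cost, ci95_qaly = ci_qaly,
                 icer = icer, status = status,
                 comparison = paste(control$strategy$name, "vs",
                                    intervention$strategy$name)),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(x$comparison, "\n")
  cat(sprintf("  Costs (£)            %8.0f (%.0f to %.0f)\n",
              x$delta_cost, x$ci95_cost[1], x$ci95_cost[2]))
  cat(sprintf("  Health outcomes (QALY) %7.3f (%.3f to %.3f)\n",
              x$delta_qaly, x$ci95_qaly[1], x$ci95_qaly[2]))
  if (is.na(x$icer)) {
    cat("  ICER (£/QALY)          ", x$status, "\n")
  } else {
    cat(sprintf("  ICER (£/QALY)      %10.0f  [%s]\n", x$icer, x$status))
  }
  invisible(x)
}
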