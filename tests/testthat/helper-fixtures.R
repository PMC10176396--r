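# shared fixtures built in code

tiny_design <- function() {
  list(
    dce_attribute("place", c("gp_surgery", "home_visit", "outpatient_clinic"),
                  reference = "gp_surgery"),
    dce_attribute("review", c("non_medicinal_only", "comprehensive"),
                  reference = "non_medicinal_only")
  )
}

# literal per-task softmax enumeration, independent of the package's
# vectorised likelihood path
brute_force_loglik <- function(beta, data) {
  X <- build_design_matrix(data)
  df <- as.data.frame(data)
  ll <- 0
  for (r in unique(df$respondent_id)) for (t in unique(df$task_id)) {
    rows <- which(df$respondent_id == r & df$task_id == t)
    if (!length(rows)) next
    ch <- df$chosen[rows]
    if (anyNA(ch) || sum(ch) != 1) next
    u <- numeric(length(rows))
    for (i in seq_along(rows))
      for (j in seq_len(ncol(X))) u[i] <- u[i] + X[rows[i], j] * beta[j]
    pr <- exp(u[ch == 1]) / sum(exp(u))
    ll <- ll + log(pr)
  }
  ll
}

ref_config <- function() {
  service_config(place = "gp_surgery", review = "non_medicinal_only",
                 support = "none", waiting = "8_weeks")
}

flat_payoffs <- function(cost = 0, utility = 1) {
  ce_payoffs(control_cost = cost, control_utility = utility)
}

# life table with a constant annual probability for both schedules
const_life_table <- function(p, ages = 60:100) {
  expand.grid(age = ages, sex = c("male", "female"),
              stringsAsFactors = FALSE) |>
    transform(annual_all_cause = p, annual_respiratory = p)
}
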