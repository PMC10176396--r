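#' Distribution assigned to an uncertain model input
#'
#' Families are restricted to those admissible for the parameter's support:
#' cycle costs (non-negative) take `gamma` or `normal`; EQ-5D utilities and
#' the uptake probability take `beta`, `logitnormal` or `normal`. Gamma and
#' beta hyperparameters are derived from the mean and standard error by
#' method of moments.
#'
#' @param param Parameter name: one of the [ce_payoffs()] parameter names
#'   (`cost_control`, `cost_effect`, `utility_control`, `utility_effect`) or
#'   `"uptake"`.
#' @param family `"gamma"`, `"beta"`, `"logitnormal"` or `"normal"`.
#' @param mean,se Mean and standard error of the input.
#' @return A `param_distribution` object.
#' @export
param_distribution <- function(param, family = c("gamma", "beta",
                                                 "logitnormal", "normal"),
                               mean, se) {
  family <- match.arg(family)
  stopifnot(is.finite(mean), is.finite(se), se >= 0)
  quantity <- if (grepl("^cost", param)) "cost" else "utility"
  ok <- switch(quantity,
               cost = c("gamma", "normal"),
               utility = c("beta", "logitnormal", "normal"))
  if (!family %in% ok)
    stop("family '", family, "' is not admissible for parameter '", param,
         "' (support allows: ", paste(ok, collapse = ", "), ")",
         call. = FALSE)
  if (family %in% c("gamma", "beta", "logitnormal") && se > 0 &&
      (mean <= 0 || (family != "gamma" && mean >= 1)))
    stop("method-of-moments ", family, " needs mean inside its support",
         call. = FALSE)
  structure(list(param = param, family = family, mean = mean, se = se),
            class = "param_distribution")
}

#' Default input distributions for a payoff set
#'
#' Gamma for arm-level cycle costs and beta for arm-level utilities
#' (method-of-moments from each parameter's mean and variance), the standard
#' choices for these supports; a utility mean outside (0, 1) falls back to a
#' normal. Optionally a beta distribution for the uptake probability.
#'
#' @param payoffs A [ce_payoffs()] object with variances.
#' @param uptake_mean,uptake_se Optional uptake uncertainty.
#' @return List of [param_distribution()] objects.
#' @export
default_psa_distributions <- function(payoffs, uptake_mean = NULL,
                                      uptake_se = 0) {
  dists <- lapply(seq_len(nrow(payoffs$params)), function(i) {
    p <- payoffs$params[i, ]
    se <- sqrt(p$var)
    if (p$quantity == "cost")
      param_distribution(p$param, "gamma", p$mean, se)
    else if (p$mean > 0 && p$mean < 1)
      param_distribution(p$param, "beta", p$mean, se)
    else
      param_distribution(p$param, "normal", p$mean, se)
  })
  if (!is.null(uptake_mean))
    dists <- c(dists, list(param_distribution("uptake", "beta",
                                              uptake_mean, uptake_se)))
  dists
}

draw_param <- function(dist, n = 1) {
  m <- dist$mean; s <- dist$se
  if (s == 0) return(rep(m, n))
  switch(dist$family,
    normal = stats::rnorm(n, m, s),
    gamma = {
      shape <- (m / s)^2
      stats::rgamma(n, shape = shape, rate = shape / m)
    },
    beta = {
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) stop("beta variance too large for its mean",
                        call. = FALSE)
      stats::rbeta(n, m * nu, (1 - m) * nu)
    },
    logitnormal = {
      # normal on the logit scale matching mean/se by delta method
      mu <- stats::qlogis(m)
      sd_l <- s / (m * (1 - m))
      stats::plogis(stats::rnorm(n, mu, sd_l))
    })
}

#' Probabilistic sensitivity analysis
#'
#' For each of `n` Monte Carlo iterations, samples every uncertain input
#' from its assigned distribution, reruns both arms of the cohort model and
#' records the incremental cost and QALY. Sampled utilities above 1 (or any
#' draw outside its parameter's support) are resampled and counted. With all
#' distributions degenerate every draw reproduces the deterministic result.
#'
#' @param cohort A [cohort_spec()].
#' @param life_table Life-table data frame.
#' @param payoffs A [ce_payoffs()] object (means used when a parameter has
#'   no distribution).
#' @param distributions List of [param_distribution()] objects; defaults to
#'   [default_psa_distributions()].
#' @param control,intervention Strategy names.
#' @param n Number of draws (study default 1000).
#' @param seed Optional integer seed.
#' @param ... Passed to [run_cohort()] (horizon, discounting, ...).
#' @return A `psa_sample`: data frame `draws` (`delta_cost`, `delta_qaly`),
#'   `n`, `seed`, `n_resampled`, and the `deterministic` [ce_result].
#' @export
draw_psa <- function(cohort, life_table, payoffs,
                     distributions = default_psa_distributions(payoffs),
                     control = "usual_care", intervention = "bs",
                     n = 1000, seed = NULL, ...) {
  stopifnot(n >= 1)
  known <- c(payoffs$params$param, "uptake")
  for (d in distributions)
    if (!d$param %in% known)
      stop("distribution targets unknown parameter '", d$param, "'",
           call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s_con <- strategy_spec(control)
  s_int <- strategy_spec(intervention)
  det <- incremental_results(
    run_cohort(cohort, s_con, life_table, payoffs, ...),
    run_cohort(cohort, s_int, life_table, payoffs, ...))

  dc <- dq <- numeric(n)
  n_resampled <- 0L
  for (i in seq_len(n)) {
    pay_i <- payoffs
    cohort_i <- cohort
    for (d in distributions) {
      repeat {
        v <- draw_param(d)
        bad <- if (d$param == "uptake") (v < 0 || v > 1)
               else if (grepl("^cost", d$param)) (v < 0)
               else (v > 1)
        if (!bad) break
        n_resampled <- n_resampled + 1L
      }
      if (d$param == "uptake") cohort_i$uptake <- v
      else pay_i$params$mean[pay_i$params$param == d$param] <- v
    }
    tr_con <- run_cohort(cohort_i, s_con, life_table, pay_i, ...)
    tr_int <- run_cohort(cohort_i, s_int, life_table, pay_i, ...)
    dc[i] <- tr_int$discounted_cost - tr_con$discounted_cost
    dq[i] <- tr_int$discounted_qaly - tr_con$discounted_qaly
  }
  structure(list(draws = data.frame(delta_cost = dc, delta_qaly = dq),
                 n = n, seed = seed, n_resampled = n_resampled,
                 deterministic = det,
                 comparison = paste(control, "vs", intervention)),
            class = "psa_sample")
}

#' @export
print.psa_sample <- function(x, ...) {
  cat(sprintf("PSA sample (%s): %d draws, mean ΔC %.0f, mean ΔQ %.4f\n",
              x$comparison, x$n, mean(x$draws$delta_cost),
              mean(x$draws$delta_qaly)))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_qaly - delta_cost` at willingness-to-pay `wtp` per
#' QALY; a draw counts toward acceptability exactly when its NMB is
#' strictly positive.
#'
#' @param delta_cost,delta_qaly Incremental cost and QALY (vectorised).
#' @param wtp Willingness to pay per QALY (>= 0).
#' @return Net monetary benefit in GBP.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stop("willingness to pay must be >= 0", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws whose net
#' monetary benefit is strictly positive (ties count as non-acceptance).
#'
#' @param sample A `psa_sample`, or a data frame with columns `delta_cost`
#'   and `delta_qaly`.
#' @param wtp_grid Non-empty vector of willingness-to-pay values (default
#'   £0–£50,000 in £1,000 steps).
#' @return A `ceac_curve` data frame: `wtp`, `acceptability`.
#' @export
ceac <- function(sample, wtp_grid = seq(0, 50000, by = 1000)) {
  draws <- if (inherits(sample, "psa_sample")) sample$draws
           else as.data.frame(sample)
  if (!nrow(draws)) stop("empty PSA sample", call. = FALSE)
  if (!length(wtp_grid)) stop("empty willingness-to-pay grid", call. = FALSE)
  acc <- vapply(wtp_grid, function(l)
    mean(net_monetary_benefit(draws$delta_cost, draws$delta_qaly, l) > 0),
    numeric(1))
  structure(data.frame(wtp = wtp_grid, acceptability = acc),
            class = c("ceac_curve", "data.frame"))
}
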