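#' Utility of a service configuration
#'
#' Adds the any-service constant to the coefficients of the configuration's
#' levels. Levels without a coefficient (the reference levels of a fitted
#' model) contribute zero; a linearly coded attribute contributes its slope
#' times the level value minus the reference value. The opt-out has utility
#' zero by normalisation.
#'
#' @param coeffs A [coefficient_set()].
#' @param config A [service_config()].
#' @return Utility `U` (scalar).
#' @export
configuration_utility <- function(coeffs, config) {
  if (config$opt_out) return(0)
  if (!is.null(coeffs$design))
    validate_config(config, coeffs$design)
  u <- coeffs$asc
  for (a in names(config$levels)) {
    lv <- config$levels[[a]]
    key <- paste0(a, ":", lv)
    attr_def <- NULL
    if (!is.null(coeffs$design)) {
      hit <- which(design_names(coeffs$design) == a)
      attr_def <- coeffs$design[[hit]]
    }
    if (!is.null(attr_def) && attr_def$coding == "linear") {
      u <- u + coeffs$betas[[a]] *
        (attr_def$values[[lv]] - attr_def$values[[attr_def$reference]])
    } else if (key %in% names(coeffs$betas)) {
      u <- u + coeffs$betas[[key]]
    } else if (is.null(coeffs$design)) {
      stop("unknown level '", lv, "' for attribute '", a,
           "': no coefficient and no design to identify it as a reference",
           call. = FALSE)
    }
  }
  unname(u)
}

# gradient of U in the coefficient order c(asc, betas); used for delta CIs
utility_gradient <- function(coeffs, config) {
  g <- stats::setNames(numeric(1 + length(coeffs$betas)),
                       c("asc", names(coeffs$betas)))
  if (config$opt_out) return(g)
  g[["asc"]] <- 1
  for (a in names(config$levels)) {
    lv <- config$levels[[a]]
    key <- paste0(a, ":", lv)
    attr_def <- NULL
    if (!is.null(coeffs$design))
      attr_def <- coeffs$design[[which(design_names(coeffs$design) == a)]]
    if (!is.null(attr_def) && attr_def$coding == "linear") {
      g[[a]] <- attr_def$values[[lv]] - attr_def$values[[attr_def$reference]]
    } else if (key %in% names(g)) {
      g[[key]] <- 1
    }
  }
  g
}

#' Uptake probability of a service configuration
#'
#' Models acceptance as a binary choice between the configured service and
#' the opt-out (utility 0): `p = exp(U) / (1 + exp(U))`. The 95% interval
#' comes from the delta method on the utility scale — `var(U) = g' V g` with
#' `g` the configuration's indicator gradient — mapped through the inverse
#' logit, which keeps the interval inside (0, 1). When the raw choice data
#' are supplied the interval is instead computed by [cluster_bootstrap()].
#'
#' @param coeffs A [coefficient_set()].
#' @param config A [service_config()].
#' @param data Optional `choice_data`; triggers the bootstrap interval.
#' @param n_boot,seed Bootstrap controls (used only with `data`).
#' @param level Interval coverage.
#' @return An `uptake_estimate`: `configuration`, `utility`, `probability`,
#'   `ci95` (`NA` when no covariance is available), `se_utility`, `method`.
#' @export
uptake_probability <- function(coeffs, config, data = NULL, n_boot = 500,
                               seed = NULL, level = 0.95) {
  u <- configuration_utility(coeffs, config)
  p <- stats::plogis(u)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(NA_real_, NA_real_)
  se_u <- NA_real_
  method <- "none"
  if (!is.null(data)) {
    bs <- cluster_bootstrap(
      data,
      function(cs) stats::plogis(configuration_utility(cs, config)),
      n_boot = n_boot, seed = seed, level = level)
    ci <- as.numeric(bs$ci[1, ])
    method <- "cluster_bootstrap"
  } else if (!is.null(coeffs$vcov)) {
    g <- utility_gradient(coeffs, config)
    se_u <- sqrt(max(0, drop(g %*% coeffs$vcov %*% g)))
    ci <- stats::plogis(u + c(-1, 1) * z * se_u)
    method <- "delta"
  }
  structure(list(configuration = config, utility = u, probability = p,
                 ci95 = ci, se_utility = se_u, method = method),
            class = "uptake_estimate")
}

#' @export
print.uptake_estimate <- function(x, ...) {
  cat(sprintf("uptake %.1f%% (U = %.3f)", 100 * x$probability, x$utility))
  if (!anyNA(x$ci95))
    cat(sprintf(", 95%% CI %.1f%% to %.1f%% [%s]",
                100 * x$ci95[1], 100 * x$ci95[2], x$method))
  cat("\n  ", format(x$configuration), "\n")
  invisible(x)
}

#' Rank service configurations by uptake probability
#'
#' Computes the uptake probability of each configuration and orders them in
#' descending probability; exact ties are broken by the deterministic
#' serialisation of the configuration (attribute:level pairs joined in
#' design order).
#'
#' @param coeffs A [coefficient_set()].
#' @param configs Non-empty list of [service_config()] objects.
#' @param ... Passed to [uptake_probability()].
#' @return Data frame with one row per configuration (descending
#'   probability): `configuration`, `utility`, `probability`, `ci_low`,
#'   `ci_high`; the full `uptake_estimate` objects are attached as the
#'   `"estimates"` attribute in the same order.
#' @export
rank_configurations <- function(coeffs, configs, ...) {
  if (!length(configs)) stop("no configurations supplied", call. = FALSE)
  est <- lapply(configs, function(cf) uptake_probability(coeffs, cf, ...))
  lab <- vapply(seq_along(configs), function(i)
    config_label(configs[[i]], coeffs$design), character(1))
  prob <- vapply(est, `[[`, numeric(1), "probability")
  ord <- order(-prob, lab)
  out <- data.frame(
    configuration = lab[ord],
    utility = vapply(est, `[[`, numeric(1), "utility")[ord],
    probability = prob[ord],
    ci_low = vapply(est, function(e) e$ci95[1], numeric(1))[ord],
    ci_high = vapply(est, function(e) e$ci95[2], numeric(1))[ord],
    stringsAsFactors = FALSE)
  attr(out, "estimates") <- est[ord]
  out
}
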