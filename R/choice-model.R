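#' Bundle preference weights into a coefficient set
#'
#' The preference model: an any-service constant (`asc`) measuring the value
#' of being offered any breathlessness service over the opt-out, plus
#' per-level utility contributions keyed `attribute:level` (or a single
#' slope keyed by the attribute name for a linearly coded attribute). Levels
#' absent from `betas` — the reference levels of a fitted model — contribute
#' zero. A coefficient file transcribed from published estimates may carry a
#' value for every level.
#'
#' @param asc Any-service constant, in utility units.
#' @param betas Named numeric vector of level coefficients.
#' @param vcov Optional covariance matrix over `c(asc, betas)`, in that
#'   order; needed for delta-method intervals.
#' @param log_likelihood,n_tasks Fit metadata (optional).
#' @param design Optional list of [dce_attribute()] objects used to validate
#'   configurations against the level space.
#' @param converged Logical fit status (optional).
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(asc, betas, vcov = NULL,
                            log_likelihood = NA_real_, n_tasks = NA_integer_,
                            design = NULL, converged = NA) {
  betas <- unlist(betas)
  stopifnot(is.numeric(asc), length(asc) == 1L)
  if (length(betas) && is.null(names(betas)))
    stop("betas must be named", call. = FALSE)
  if (!is.null(vcov)) {
    p <- 1L + length(betas)
    if (!is.matrix(vcov) || any(dim(vcov) != p))
      stop("vcov must be ", p, "x", p, " (asc first, then betas)",
           call. = FALSE)
    ev <- eigen(((vcov + t(vcov)) / 2), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("vcov is not positive semi-definite", call. = FALSE)
    dimnames(vcov) <- list(c("asc", names(betas)), c("asc", names(betas)))
  }
  if (!is.null(design)) check_design(design)
  structure(list(asc = asc, betas = betas, vcov = vcov,
                 log_likelihood = log_likelihood, n_tasks = n_tasks,
                 design = design, converged = converged),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  est <- c(asc = x$asc, x$betas)
  tab <- data.frame(estimate = round(est, 4))
  if (!is.null(x$vcov)) {
    se <- sqrt(diag(x$vcov))
    tab$se <- round(se, 4)
    tab$ci_low <- round(est - stats::qnorm(0.975) * se, 4)
    tab$ci_high <- round(est + stats::qnorm(0.975) * se, 4)
  }
  print(tab)
  if (is.finite(x$log_likelihood))
    cat("log-likelihood:", format(x$log_likelihood), "over", x$n_tasks,
        "tasks\n")
  invisible(x)
}

# Internal model frame: rows sorted so each answered task occupies a
# contiguous block of 3; unanswered tasks are dropped from the likelihood.
clogit_parts <- function(data) {
  X <- build_design_matrix(data)
  key <- interaction(data$respondent_id, data$task_id, drop = TRUE)
  chosen <- ifelse(is.na(data$chosen), 0, data$chosen)
  answered <- rowsum(chosen, key)[, 1] == 1
  keep <- answered[key]
  X <- X[keep, , drop = FALSE]
  key <- droplevels(key[keep])
  ord <- order(as.integer(key))
  list(X = X[ord, , drop = FALSE],
       task = as.integer(key)[ord],
       y = chosen[keep][ord],
       respondent = data$respondent_id[keep][ord],
       n_tasks = nlevels(key))
}

# log-likelihood, score and Fisher information for a 3-alternative
# conditional logit; exploits the fixed task size for speed.
clogit_core <- function(beta, parts, what = "ll") {
  eta <- drop(parts$X %*% beta)
  M <- matrix(eta, nrow = 3L)                    # alternatives x tasks
  mx <- pmax(M[1L, ], M[2L, ], M[3L, ])
  E <- exp(M - rep(mx, each = 3L))
  lse <- mx + log(.colSums(E, 3L, ncol(M)))
  ll <- sum(eta[parts$y == 1]) - sum(lse)
  if (what == "ll") return(ll)
  p <- as.vector(E / rep(.colSums(E, 3L, ncol(M)), each = 3L))
  resid <- parts$y - p
  score <- drop(crossprod(parts$X, resid))
  if (what == "score") return(list(ll = ll, score = score, p = p))
  PX <- parts$X * p
  Mbar <- rowsum(PX, parts$task)                 # per-task sum p_i x_i
  info <- crossprod(parts$X, PX) - crossprod(Mbar)
  list(ll = ll, score = score, info = info, resid = resid)
}

#' Conditional logit log-likelihood
#'
#' Sum over answered tasks of the log softmax probability of the chosen
#' alternative, with utilities `U = design row . beta`. Stabilised by
#' subtracting the per-task maximum utility before exponentiating, so the
#' value is finite for any finite inputs. Tasks where no alternative was
#' chosen are excluded.
#'
#' @param beta Numeric vector, one entry per design-matrix column
#'   (`asc` first).
#' @param data A `choice_data` object.
#' @return The log-likelihood (scalar).
#' @export
clogit_loglik <- function(beta, data) {
  parts <- clogit_parts(data)
  if (length(beta) != ncol(parts$X))
    stop("beta has length ", length(beta), " but the design matrix has ",
         ncol(parts$X), " columns", call. = FALSE)
  clogit_core(beta, parts, "ll")
}

#' Fit the conditional logit preference model
#'
#' Maximises the conditional logit likelihood by Newton–Raphson with
#' analytic score and observed information (the likelihood is concave, so
#' the optimum is global). The covariance of the estimates is the inverse
#' information; because each respondent contributes several tasks, a
#' cluster-robust (sandwich) covariance grouped by respondent is also
#' computed and used by default for reporting.
#'
#' @param data A `choice_data` object with at least one answered task.
#' @param start Optional start values (default: zero vector).
#' @param tol Convergence tolerance on the score's infinity norm.
#' @param max_iter Maximum Newton iterations.
#' @param cluster_se Logical; attach the respondent-clustered covariance to
#'   the returned coefficient set (the model-based covariance is always kept
#'   alongside).
#' @param columns Optional character vector of design-matrix columns to fit
#'   (must include `"asc"`); restricting columns fits a nested model, e.g.
#'   the any-service constant alone.
#' @return An object of class `clogit_fit`: `coefficients` (a
#'   [coefficient_set()]), `vcov_model`, `vcov_cluster`, `log_likelihood`,
#'   `null_log_likelihood`, `n_tasks`, `n_respondents`, `converged`,
#'   `n_iterations`, `gradient_norm`, `separation`.
#' @export
fit_conditional_logit <- function(data, start = NULL, tol = 1e-6,
                                  max_iter = 200, cluster_se = TRUE,
                                  columns = NULL) {
  parts <- clogit_parts(data)
  if (parts$n_tasks < 1) stop("no answered tasks", call. = FALSE)
  if (!is.null(columns)) {
    if (!"asc" %in% columns)
      stop("a restricted model must keep the any-service constant",
           call. = FALSE)
    bad <- setdiff(columns, colnames(parts$X))
    if (length(bad))
      stop("unknown design column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    parts$X <- parts$X[, columns, drop = FALSE]
  }
  p <- ncol(parts$X)
  # separability: a column constant within every task carries no information
  within_var <- apply(parts$X, 2L, function(col)
    max(abs(col - rep(colMeans(matrix(col, nrow = 3L))[parts$task], 1))))
  if (any(within_var < 1e-12))
    stop("design column(s) constant within every task: ",
         paste(colnames(parts$X)[within_var < 1e-12], collapse = ", "),
         call. = FALSE)

  beta <- if (is.null(start)) numeric(p) else {
    stopifnot(length(start) == p); as.numeric(start)
  }
  ll0 <- clogit_core(numeric(p), parts, "ll")
  cur <- clogit_core(beta, parts, "full")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gnorm <- max(abs(cur$score))
    if (gnorm < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$info, cur$score), error = function(e) NULL)
    if (is.null(step)) break                     # singular information
    halve <- 0L
    repeat {
      cand <- beta + step
      nxt <- clogit_core(cand, parts, "full")
      if (nxt$ll >= cur$ll - 1e-12 || halve >= 30L) break
      step <- step / 2
      halve <- halve + 1L
    }
    beta <- cand
    cur <- nxt
  }
  gnorm <- max(abs(cur$score))
  if (gnorm < tol) converged <- TRUE
  separation <- max(abs(beta)) > 10
  if (separation)
    warning("very large coefficient(s); possible (quasi-)separation — ",
            "the likelihood may be unbounded", call. = FALSE)

  vcov_model <- tryCatch(solve(cur$info), error = function(e)
    matrix(NA_real_, p, p))
  dimnames(vcov_model) <- list(colnames(parts$X), colnames(parts$X))
  U <- rowsum(parts$X * cur$resid, parts$respondent)   # per-cluster scores
  vcov_cluster <- vcov_model %*% crossprod(U) %*% vcov_model
  dimnames(vcov_cluster) <- dimnames(vcov_model)

  names(beta) <- colnames(parts$X)
  use_vcov <- if (cluster_se) vcov_cluster else vcov_model
  coeffs <- coefficient_set(asc = beta[["asc"]], betas = beta[-1],
                            vcov = regularise_psd(use_vcov),
                            log_likelihood = cur$ll,
                            n_tasks = parts$n_tasks,
                            design = attr(data, "design"),
                            converged = converged)
  structure(list(coefficients = coeffs,
                 vcov_model = vcov_model, vcov_cluster = vcov_cluster,
                 log_likelihood = cur$ll, null_log_likelihood = ll0,
                 n_tasks = parts$n_tasks,
                 n_respondents = length(unique(parts$respondent)),
                 converged = converged, n_iterations = iter,
                 gradient_norm = gnorm, separation = separation),
            class = "clogit_fit")
}

# clip tiny negative eigenvalues arising from finite-sample sandwich algebra
regularise_psd <- function(V) {
  if (anyNA(V)) return(V)
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) >= 0) return(V)
  W <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  dimnames(W) <- dimnames(V)
  W
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat("conditional logit fit:", x$n_tasks, "tasks,", x$n_respondents,
      "respondents;", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iterations, "iterations\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
logLik.clogit_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = 1L + length(object$coefficients$betas), class = "logLik")
}

#' Likelihood-ratio test between nested conditional logit fits
#'
#' Used for subgroup comparisons: the full model fits each subgroup its own
#' coefficient vector (its log-likelihood is the sum of the per-subgroup
#' fits), the nested model pools the subgroups.
#'
#' @param full,nested `clogit_fit` objects or numeric log-likelihoods. For a
#'   subgroup test, pass the full model as a list of per-subgroup fits; the
#'   log-likelihoods are summed.
#' @param df Degrees of freedom; when both arguments are fits it defaults to
#'   the difference in parameter counts.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lr_test <- function(full, nested, df = NULL) {
  ll_of <- function(x) {
    if (is.numeric(x)) return(sum(x))
    if (inherits(x, "clogit_fit")) {
      if (!x$converged) stop("fit did not converge", call. = FALSE)
      return(x$log_likelihood)
    }
    if (is.list(x)) return(sum(vapply(x, ll_of, numeric(1))))
    stop("cannot extract a log-likelihood", call. = FALSE)
  }
  np_of <- function(x) {
    if (inherits(x, "clogit_fit")) return(1L + length(x$coefficients$betas))
    if (is.list(x) && !is.numeric(x))
      return(sum(vapply(x, np_of, numeric(1))))
    NA_integer_
  }
  ll_full <- ll_of(full)
  ll_nested <- ll_of(nested)
  if (ll_full < ll_nested - 1e-6)
    stop("full-model log-likelihood (", format(ll_full),
         ") is below the nested model's (", format(ll_nested),
         "); optimisation has failed", call. = FALSE)
  if (is.null(df)) {
    df <- np_of(full) - np_of(nested)
    if (is.na(df)) stop("supply `df` when passing raw log-likelihoods",
                        call. = FALSE)
  }
  stat <- max(0, 2 * (ll_full - ll_nested))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Cluster bootstrap over respondents
#'
#' Resamples respondents (the independent units) with replacement, refits
#' the conditional logit on each resample and returns percentile intervals
#' of an arbitrary statistic of the fitted coefficients. Draws whose refit
#' fails to converge are discarded and counted; more than 10% discards
#' raises a warning.
#'
#' @param data A `choice_data` object.
#' @param statistic Function mapping a [coefficient_set()] to a numeric
#'   scalar or vector.
#' @param n_boot Number of bootstrap draws (at least 100).
#' @param seed Optional integer seed; fixed seed gives identical intervals.
#' @param level Interval coverage (default 0.95).
#' @return List with `ci` (matrix: statistic components x `c(low, high)`),
#'   `draws` (matrix of retained statistics), `n_failed`.
#' @export
cluster_bootstrap <- function(data, statistic, n_boot = 500, seed = NULL,
                              level = 0.95) {
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  design <- attr(data, "design")
  ids <- unique(data$respondent_id)
  by_resp <- split(seq_len(nrow(data)), data$respondent_id)
  draws <- vector("list", n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    pick <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(by_resp[as.character(pick)], use.names = FALSE)
    boot_df <- as.data.frame(data)[idx, , drop = FALSE]
    # relabel so repeated respondents stay distinct clusters
    reps <- vapply(by_resp[as.character(pick)], length, integer(1))
    boot_df$respondent_id <- rep(seq_along(pick), reps)
    fit <- tryCatch(
      suppressWarnings(fit_conditional_logit(choice_data(boot_df, design),
                                             cluster_se = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_failed <- n_failed + 1L; next }
    draws[[b]] <- statistic(fit$coefficients)
  }
  draws <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  if (n_failed > 0.1 * n_boot)
    warning(n_failed, " of ", n_boot, " bootstrap refits discarded",
            call. = FALSE)
  a <- (1 - level) / 2
  ci <- t(apply(draws, 2L, stats::quantile, probs = c(a, 1 - a),
                names = FALSE, type = 7))
  colnames(ci) <- c("low", "high")
  list(ci = ci, draws = draws, n_failed = n_failed)
}
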