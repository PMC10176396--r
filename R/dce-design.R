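#' Define a service attribute
#'
#' An attribute of a breathlessness service (e.g. place of consultation) with
#' its levels, a reference level and a coding scheme. Dummy coding contributes
#' one design-matrix column per non-reference level; linear coding contributes
#' a single numeric column holding the level value centred at the reference
#' value (useful for waiting time in weeks).
#'
#' @param name Attribute identifier (single string).
#' @param levels Character vector of at least two unique level identifiers.
#' @param reference Reference level; must be one of `levels`. Its utility
#'   contribution is normalised to zero under dummy coding.
#' @param coding `"dummy"` (default) or `"linear"`.
#' @param values Named numeric vector giving the numeric value of each level;
#'   required when `coding = "linear"`.
#' @return An object of class `dce_attribute`.
#' @examples
#' dce_attribute("waiting", c("2_weeks", "4_weeks", "8_weeks"),
#'               reference = "8_weeks")
#' @export
dce_attribute <- function(name, levels, reference = levels[[1]],
                          coding = c("dummy", "linear"), values = NULL) {
  coding <- match.arg(coding)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L)
    stop("attribute '", name, "' needs at least 2 levels", call. = FALSE)
  if (anyDuplicated(levels))
    stop("attribute '", name, "' has duplicated level names", call. = FALSE)
  if (!reference %in% levels)
    stop("reference level '", reference, "' is not a level of '", name, "'",
         call. = FALSE)
  if (coding == "linear") {
    if (is.null(values) || !all(levels %in% names(values)))
      stop("linear coding of '", name, "' requires a named `values` entry ",
           "for every level", call. = FALSE)
    values <- values[levels]
  }
  structure(list(name = name, levels = levels, reference = reference,
                 coding = coding, values = values),
            class = "dce_attribute")
}

#' Default attribute catalogue for a breathlessness service
#'
#' Place of consultation, nature of treatment review, additional support and
#' waiting time to the first appointment. The two expectation attributes
#' (change in breathlessness, change in healthcare use) are held fixed across
#' all configurations and are therefore absorbed into the any-service
#' constant rather than varied in the design. Waiting time defaults to dummy
#' coding with 8 weeks as reference; linear coding (in weeks) supports
#' willingness-to-wait analyses.
#'
#' @param waiting_coding `"dummy"` (default) or `"linear"`.
#' @return List of [dce_attribute()] objects.
#' @export
default_attributes <- function(waiting_coding = c("dummy", "linear")) {
  waiting_coding <- match.arg(waiting_coding)
  list(
    dce_attribute("place",
                  c("gp_surgery", "home_visit", "outpatient_clinic"),
                  reference = "gp_surgery"),
    dce_attribute("review",
                  c("non_medicinal_only", "comprehensive"),
                  reference = "non_medicinal_only"),
    dce_attribute("support",
                  c("none", "social_worker_only", "therapists_and_social_worker"),
                  reference = "none"),
    dce_attribute("waiting",
                  c("2_weeks", "4_weeks", "8_weeks"),
                  reference = "8_weeks",
                  coding = waiting_coding,
                  values = c("2_weeks" = 2, "4_weeks" = 4, "8_weeks" = 8))
  )
}

design_names <- function(design) vapply(design, `[[`, character(1), "name")

check_design <- function(design) {
  if (!length(design)) stop("empty attribute design", call. = FALSE)
  ok <- vapply(design, inherits, logical(1), "dce_attribute")
  if (!all(ok)) stop("design must be a list of dce_attribute objects",
                     call. = FALSE)
  nm <- design_names(design)
  if (anyDuplicated(nm)) stop("duplicated attribute names in design",
                              call. = FALSE)
  invisible(design)
}

#' Describe one service configuration
#'
#' Either one level per attribute of the design, or the opt-out ("neither")
#' alternative whose utility is normalised to zero.
#'
#' @param ... Named level assignments, `attribute = "level"`. Alternatively a
#'   single named character vector or list.
#' @param opt_out Logical; if `TRUE` no levels may be given.
#' @return An object of class `service_config`.
#' @examples
#' service_config(place = "gp_surgery", review = "non_medicinal_only",
#'                support = "none", waiting = "8_weeks")
#' opt_out_config()
#' @export
service_config <- function(..., opt_out = FALSE) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.list(dots[[1]]) || is.character(dots[[1]])))
    dots <- as.list(dots[[1]])
  if (opt_out) {
    if (length(dots))
      stop("an opt-out configuration carries no attribute levels",
           call. = FALSE)
    return(structure(list(levels = character(0), opt_out = TRUE),
                     class = "service_config"))
  }
  if (!length(dots) || is.null(names(dots)) || any(!nzchar(names(dots))))
    stop("attribute levels must be named", call. = FALSE)
  lv <- vapply(dots, as.character, character(1))
  structure(list(levels = lv, opt_out = FALSE), class = "service_config")
}

#' @rdname service_config
#' @export
opt_out_config <- function() service_config(opt_out = TRUE)

#' @export
format.service_config <- function(x, ...) {
  if (x$opt_out) return("<opt-out>")
  paste(paste0(names(x$levels), "=", x$levels), collapse = ", ")
}

#' @export
print.service_config <- function(x, ...) {
  cat("service configuration:", format(x), "\n")
  invisible(x)
}

# deterministic serialisation used for tie-breaking and labels
config_label <- function(config, design = NULL) {
  if (config$opt_out) return("opt_out")
  lv <- config$levels
  if (!is.null(design)) lv <- lv[intersect(design_names(design), names(lv))]
  paste(paste0(names(lv), ":", lv), collapse = "|")
}

validate_config <- function(config, design, where = "configuration") {
  if (config$opt_out) return(invisible(config))
  nm <- design_names(design)
  missing <- setdiff(nm, names(config$levels))
  if (length(missing))
    stop(where, " is missing attribute(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(config$levels), nm)
  if (length(extra))
    stop(where, " has unknown attribute(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (a in design) {
    lv <- config$levels[[a$name]]
    if (!lv %in% a$levels)
      stop("unknown level '", lv, "' for attribute '", a$name, "'",
           call. = FALSE)
  }
  invisible(config)
}

#' Assemble a choice dataset
#'
#' Validates long-format choice records (one row per alternative) against an
#' attribute design and returns a `choice_data` object. Every task must hold
#' exactly three alternatives — two distinct service configurations and one
#' opt-out — with at most one alternative marked chosen. Tasks where no
#' alternative is chosen are kept but excluded from any likelihood.
#'
#' @param records Data frame with columns `respondent_id`, `task_id`,
#'   `alt_id`, `chosen` (0/1 or `NA`), `is_opt_out` (0/1) and one column per
#'   attribute holding level identifiers (`NA` on opt-out rows).
#' @param design List of [dce_attribute()] objects.
#' @return A `choice_data` object: the validated data frame with the design
#'   attached as an attribute.
#' @export
choice_data <- function(records, design) {
  check_design(design)
  records <- as.data.frame(records)
  need <- c("respondent_id", "task_id", "alt_id", "chosen", "is_opt_out",
            design_names(design))
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("choice records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  records$is_opt_out <- as.integer(records$is_opt_out)
  if (!all(records$is_opt_out %in% c(0L, 1L)))
    stop("is_opt_out must be 0/1", call. = FALSE)
  if (!all(is.na(records$chosen) | records$chosen %in% c(0, 1)))
    stop("chosen must be 0/1 or NA", call. = FALSE)

  # validate levels on service rows
  svc <- records$is_opt_out == 0L
  for (a in design) {
    lv <- records[[a$name]][svc]
    bad <- !is.na(lv) & !lv %in% a$levels
    if (any(bad))
      stop("unknown level '", lv[bad][1], "' for attribute '", a$name, "'",
           call. = FALSE)
    if (anyNA(lv))
      stop("missing level for attribute '", a$name,
           "' on a service alternative", call. = FALSE)
  }

  key <- interaction(records$respondent_id, records$task_id, drop = TRUE)
  sizes <- tabulate(key)
  if (any(sizes != 3L))
    stop("every task must have exactly 3 alternatives", call. = FALSE)
  n_opt <- rowsum(records$is_opt_out, key)
  if (any(n_opt != 1L))
    stop("every task must contain exactly one opt-out alternative",
         call. = FALSE)
  n_chosen <- rowsum(ifelse(is.na(records$chosen), 0, records$chosen), key)
  if (any(n_chosen > 1))
    stop("a task has more than one alternative marked chosen", call. = FALSE)

  ord <- order(records$respondent_id, records$task_id, records$alt_id)
  records <- records[ord, , drop = FALSE]

  # the two service alternatives must differ in at least one attribute;
  # after sorting, each task's service rows are consecutive
  svc_rows <- which(records$is_opt_out == 0L)
  lv_mat <- do.call(paste, c(records[design_names(design)], sep = "\r"))
  odd <- svc_rows[seq(1L, length(svc_rows), by = 2L)]
  even <- svc_rows[seq(2L, length(svc_rows), by = 2L)]
  if (any(lv_mat[odd] == lv_mat[even]))
    stop("a task pairs two identical service configurations", call. = FALSE)
  rownames(records) <- NULL
  structure(records, design = design, class = c("choice_data", "data.frame"))
}

#' @export
print.choice_data <- function(x, ...) {
  d <- attr(x, "design")
  key <- interaction(x$respondent_id, x$task_id, drop = TRUE)
  answered <- sum(rowsum(ifelse(is.na(x$chosen), 0, x$chosen), key) == 1)
  cat("choice data:", nrow(x), "alternatives,", nlevels(key), "tasks (",
      answered, "answered ),",
      length(unique(x$respondent_id)), "respondents,",
      length(d), "attributes\n")
  invisible(x)
}

#' Count tasks and likelihood observations
#'
#' @param data A `choice_data` object.
#' @return Named list: `n_tasks`, `n_answered_tasks`, `n_respondents`,
#'   `n_rows` (all alternatives) and `n_observations` (alternatives belonging
#'   to answered tasks — the rows that enter the likelihood).
#' @export
choice_counts <- function(data) {
  key <- interaction(data$respondent_id, data$task_id, drop = TRUE)
  chosen <- ifelse(is.na(data$chosen), 0, data$chosen)
  answered <- rowsum(chosen, key)[, 1] == 1
  list(n_tasks = nlevels(key),
       n_answered_tasks = sum(answered),
       n_respondents = length(unique(data$respondent_id)),
       n_rows = nrow(data),
       n_observations = 3L * sum(answered))
}

#' Generate random paired choice tasks
#'
#' Draws, for each respondent and task, two distinct service configurations
#' uniformly over the level space and adds the opt-out alternative. The
#' `chosen` column is left `NA`; [simulate_choice_data()] fills it from a
#' known utility vector. With a fixed seed the output is bit-identical
#' across runs.
#'
#' @param design List of [dce_attribute()] objects.
#' @param n_respondents,n_tasks Numbers of respondents and tasks per
#'   respondent (the study format used six tasks each).
#' @param seed Optional integer seed.
#' @return A `choice_data` object with `chosen = NA`.
#' @export
generate_choice_tasks <- function(design, n_respondents, n_tasks = 6,
                                  seed = NULL) {
  check_design(design)
  stopifnot(n_respondents >= 1, n_tasks >= 1)
  n_space <- prod(vapply(design, function(a) length(a$levels), numeric(1)))
  if (n_space < 2)
    stop("the design admits a single configuration; distinct pairs ",
         "cannot be formed", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- n_respondents * n_tasks
  draw <- function() {
    out <- lapply(design, function(a)
      a$levels[sample.int(length(a$levels), n, replace = TRUE)])
    names(out) <- design_names(design)
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  A <- draw()
  B <- draw()
  same <- function(x, y)
    do.call(paste, c(x, sep = "\r")) == do.call(paste, c(y, sep = "\r"))
  dup <- same(A, B)
  while (any(dup)) {               # redraw clashing partners only
    k <- which(dup)
    repl <- lapply(design, function(a)
      a$levels[sample.int(length(a$levels), length(k), replace = TRUE)])
    names(repl) <- design_names(design)
    B[k, ] <- as.data.frame(repl, stringsAsFactors = FALSE)
    dup[k] <- same(A[k, , drop = FALSE], B[k, , drop = FALSE])
  }

  base <- data.frame(respondent_id = rep(seq_len(n_respondents),
                                         each = n_tasks),
                     task_id = rep(seq_len(n_tasks), n_respondents))
  mk <- function(alt, lv, opt) {
    out <- cbind(base, alt_id = alt, chosen = NA_real_,
                 is_opt_out = as.integer(opt))
    if (opt) {
      for (nm in design_names(design)) out[[nm]] <- NA_character_
    } else out <- cbind(out, lv)
    out
  }
  records <- rbind(mk(1L, A, FALSE), mk(2L, B, FALSE), mk(3L, NULL, TRUE))
  choice_data(records, design)
}

#' Build the conditional-logit design matrix
#'
#' One row per alternative, aligned with the rows of `data`. The first
#' column (`asc`) is the any-service alternative-specific constant: 1 on
#' service rows, 0 on the opt-out, whose utility is normalised to zero, so
#' opt-out rows are all-zero. Dummy-coded attributes contribute one column
#' per non-reference level, labelled `attribute:level`; linear attributes one
#' numeric column (level value minus reference value) labelled by the
#' attribute name.
#'
#' @param data A `choice_data` object.
#' @return Numeric matrix with column names.
#' @export
build_design_matrix <- function(data) {
  design <- attr(data, "design")
  check_design(design)
  svc <- data$is_opt_out == 0L
  cols <- list(asc = as.numeric(svc))
  for (a in design) {
    lv <- data[[a$name]]
    if (a$coding == "dummy") {
      for (l in setdiff(a$levels, a$reference))
        cols[[paste0(a$name, ":", l)]] <- as.numeric(svc & !is.na(lv) & lv == l)
    } else {
      v <- a$values[lv] - a$values[[a$reference]]
      v[!svc | is.na(lv)] <- 0
      cols[[a$name]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}

#' Decode one design-matrix row back into a configuration
#'
#' Inverse of the encoding in [build_design_matrix()]; used to verify the
#' encoding round-trips exactly.
#'
#' @param row Numeric vector named as the design-matrix columns.
#' @param design List of [dce_attribute()] objects.
#' @return A [service_config()].
#' @export
decode_design_row <- function(row, design) {
  check_design(design)
  if (row[["asc"]] == 0) return(opt_out_config())
  lv <- character(0)
  for (a in design) {
    if (a$coding == "dummy") {
      hit <- a$reference
      for (l in setdiff(a$levels, a$reference))
        if (row[[paste0(a$name, ":", l)]] == 1) hit <- l
      lv[[a$name]] <- hit
    } else {
      val <- row[[a$name]] + a$values[[a$reference]]
      lv[[a$name]] <- a$levels[which.min(abs(a$values - val))]
    }
  }
  service_config(lv)
}
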