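#' Read and write choice data as long-format CSV
#'
#' Columns: `respondent_id`, `task_id`, `alt_id`, `chosen` (0/1, empty for a
#' non-response), `is_opt_out` (0/1), then one column per attribute holding
#' the level identifier (empty on opt-out rows).
#'
#' @param path File path.
#' @param design List of [dce_attribute()] objects the records must match.
#' @return [read_choice_csv()] returns a `choice_data` object;
#'   [write_choice_csv()] returns `path` invisibly.
#' @export
read_choice_csv <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (nm in c("respondent_id", "task_id", "alt_id", "chosen", "is_opt_out"))
    if (nm %in% names(df)) df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  for (a in design_names(design)) df[[a]][!nzchar(trimws(df[[a]]))] <- NA
  choice_data(df, design)
}

#' @rdname read_choice_csv
#' @param data A `choice_data` object.
#' @export
write_choice_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write an attribute design configuration (YAML or JSON)
#'
#' The file holds a list of attributes, each with `name`, `levels`,
#' `reference`, `coding` and, for linear coding, `values`.
#'
#' @param path File path; format chosen by extension (`.json` vs `.yaml`/`.yml`).
#' @return A list of [dce_attribute()] objects.
#' @export
read_design_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(raw$attributes)) raw <- raw$attributes
  design <- lapply(raw, function(a) {
    vals <- a$values
    if (!is.null(vals)) vals <- unlist(vals)
    dce_attribute(a$name, unlist(a$levels),
                  reference = a$reference %||% a$levels[[1]],
                  coding = a$coding %||% "dummy",
                  values = vals)
  })
  check_design(design)
}

#' @rdname read_design_config
#' @param design List of [dce_attribute()] objects.
#' @export
write_design_config <- function(design, path) {
  check_design(design)
  out <- list(attributes = lapply(design, function(a) {
    x <- list(name = a$name, levels = as.list(a$levels),
              reference = a$reference, coding = a$coding)
    if (!is.null(a$values)) x$values <- as.list(a$values)
    x
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write fitted or user-supplied coefficient sets as JSON
#'
#' The schema mirrors the fitting output: `asc`, `betas` (named by
#' `attribute:level`), `se`, `ci95`, `vcov` (ordered `asc` first, then the
#' betas), `log_likelihood`, `n_tasks`, `converged`, plus the attribute
#' design so configurations can be validated. Coefficient files transcribed
#' from published figures may give a value for every level of an attribute;
#' levels missing from `betas` contribute zero utility.
#'
#' @param path File path.
#' @return A [coefficient_set()].
#' @export
read_coefficients <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  design <- NULL
  if (!is.null(raw$design)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(list(attributes = raw$design), tmp,
                         auto_unbox = TRUE)
    design <- read_design_config(tmp)
  }
  vcov <- NULL
  if (!is.null(raw$vcov)) {
    vcov <- if (is.matrix(raw$vcov)) raw$vcov
            else do.call(rbind, lapply(raw$vcov, unlist))
    dimnames(vcov) <- list(c("asc", names(raw$betas)),
                           c("asc", names(raw$betas)))
  }
  coefficient_set(asc = raw$asc, betas = unlist(raw$betas), vcov = vcov,
                  log_likelihood = raw$log_likelihood %||% NA_real_,
                  n_tasks = raw$n_tasks %||% NA_integer_,
                  design = design)
}

#' @rdname read_coefficients
#' @param coeffs A [coefficient_set()].
#' @export
write_coefficients <- function(coeffs, path) {
  se <- ci <- NULL
  if (!is.null(coeffs$vcov)) {
    sd <- sqrt(diag(coeffs$vcov))
    est <- c(asc = coeffs$asc, coeffs$betas)
    se <- as.list(sd)
    ci <- lapply(seq_along(est), function(i)
      c(est[i] - stats::qnorm(0.975) * sd[i],
        est[i] + stats::qnorm(0.975) * sd[i]))
    names(ci) <- names(est)
  }
  out <- list(asc = coeffs$asc, betas = as.list(coeffs$betas),
              se = se, ci95 = ci,
              vcov = if (!is.null(coeffs$vcov))
                lapply(seq_len(nrow(coeffs$vcov)),
                       function(i) unname(coeffs$vcov[i, ])),
              log_likelihood = coeffs$log_likelihood,
              n_tasks = coeffs$n_tasks,
              converged = coeffs$converged %||% NA)
  if (!is.null(coeffs$design))
    out$design <- lapply(coeffs$design, function(a) {
      x <- list(name = a$name, levels = as.list(a$levels),
                reference = a$reference, coding = a$coding)
      if (!is.null(a$values)) x$values <- as.list(a$values)
      x
    })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read and write a life table CSV
#'
#' Columns `age`, `sex`, `annual_all_cause`, `annual_respiratory` with
#' annual death probabilities in `[0, 1]`.
#'
#' @param path File path.
#' @return A validated life-table data frame.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(df)
}

#' @rdname read_life_table
#' @param life_table Life-table data frame.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(validate_life_table(life_table), path, row.names = FALSE)
  invisible(path)
}
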