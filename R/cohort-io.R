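#' Cohort table format
#'
#' A cohort is a long-format data.frame with one row per clinical visit and
#' columns:
#' \describe{
#'   \item{patient_id}{patient identifier (character or integer)}
#'   \item{centre}{clinical centre identifier}
#'   \item{age_years}{decimal age at the visit, strictly positive}
#'   \item{<domain>}{one integer column per domain of [npc_domains()]}
#'   \item{seizure_observed}{0/1 or logical; seizure recorded at this visit}
#'   \item{treatment_start_age}{decimal years, `NA` if never treated}
#' }
#' Rows for one patient must have strictly increasing ages. A patient is in
#' the seizure group when any of their visits has `seizure_observed` true.
#'
#' @name cohort-format
NULL

cohort_columns <- function() {
  c("patient_id", "centre", "age_years", npc_domains()$domain,
    "seizure_observed", "treatment_start_age")
}

#' Read a cohort CSV
#'
#' Reads and validates a long-format visit table (see [cohort-format]).
#' Rows are sorted by patient then age. Errors name the offending rows.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return A validated cohort data.frame.
#' @seealso [write_cohort()], [generate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(x)
}

#' Write a cohort CSV
#'
#' @param cohort A cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort table
#'
#' Checks the column schema, positive numeric ages, duplicate
#' (patient, age) rows, and per-domain score ranges; sorts by patient and
#' age and normalises `seizure_observed` to logical.
#'
#' @param cohort A candidate cohort data.frame.
#' @return The validated, sorted cohort.
#' @export
validate_cohort <- function(cohort) {
  need <- setdiff(cohort_columns(), "treatment_start_age")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0L) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cohort$treatment_start_age)) cohort$treatment_start_age <- NA_real_
  age <- suppressWarnings(as.numeric(cohort$age_years))
  if (anyNA(age)) {
    stop("non-numeric age_years at row(s): ",
         paste(utils::head(which(is.na(age)), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(age <= 0)) {
    stop("age_years must be > 0 (ASIS is undefined at age 0); offending row(s): ",
         paste(utils::head(which(age <= 0), 5L), collapse = ", "), call. = FALSE)
  }
  cohort$age_years <- age
  key <- paste(cohort$patient_id, format(cohort$age_years, digits = 12))
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, age_years) row(s): ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "),
         call. = FALSE)
  }
  bad <- validate_visits(cohort)
  if (nrow(bad) > 0L) {
    stop("invalid score(s), e.g. row ", bad$row[1L], ": ", bad$domain[1L],
         " = ", bad$value[1L], " (allowed ", bad$allowed[1L], ")",
         call. = FALSE)
  }
  cohort$seizure_observed <- as.logical(cohort$seizure_observed)
  cohort <- cohort[order(cohort$patient_id, cohort$age_years), , drop = FALSE]
  rownames(cohort) <- NULL
  cohort
}

#' First visit of each patient
#'
#' @param cohort A cohort data.frame.
#' @return One row per patient: the earliest visit, in patient order.
#' @export
first_visits <- function(cohort) {
  ord <- order(cohort$patient_id, cohort$age_years)
  cohort <- cohort[ord, , drop = FALSE]
  out <- cohort[!duplicated(cohort$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-patient metadata
#'
#' @param cohort A cohort data.frame.
#' @return One row per patient with `patient_id`, `centre`, `n_visits`,
#'   `first_age`, `last_age`, `span_years` (last minus first age) and
#'   `seizure_group` (any visit with a seizure).
#' @export
patient_table <- function(cohort) {
  sp <- split(cohort, cohort$patient_id)
  out <- do.call(rbind, lapply(sp, function(p) {
    data.frame(
      patient_id = p$patient_id[1L],
      centre = p$centre[1L],
      n_visits = nrow(p),
      first_age = min(p$age_years),
      last_age = max(p$age_years),
      span_years = max(p$age_years) - min(p$age_years),
      seizure_group = any(p$seizure_observed),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

# round-half-up to `digits` decimals; base round() is round-half-even
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
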