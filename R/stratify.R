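#' Define a trial inclusion criterion
#'
#' A criterion is either an age band or an ASIS band, evaluated at each
#' patient's first visit; band endpoints are inclusive on both sides.
#' Age-based criteria can additionally require neurological signs
#' (composite severity > 0 at first visit), as real NPC trials do to
#' exclude pre-symptomatic patients. ASIS bands with a positive lower
#' bound imply signs already.
#'
#' @param name Short identifier.
#' @param kind `"age_band"` or `"asis_band"`.
#' @param lower,upper Inclusive band limits (`upper = Inf` for open-ended).
#' @param require_signs Demand severity > 0 at first visit.
#' @return An object of class `inclusion_criterion`.
#' @export
inclusion_criterion <- function(name, kind = c("age_band", "asis_band"),
                                lower, upper = Inf, require_signs = FALSE) {
  kind <- match.arg(kind)
  if (lower > upper) stop("lower > upper", call. = FALSE)
  structure(list(name = name, kind = kind, lower = lower, upper = upper,
                 require_signs = require_signs),
            class = "inclusion_criterion")
}

#' Built-in catalogue of trial inclusion criteria
#'
#' The nine canonical criteria: three age bands used by real NPC trials
#' (miglustat, > 12 years; arimoclomol, 2--18; intrathecal cyclodextrin,
#' 4--21; each with a neurological-sign requirement) and six ASIS bands
#' (0.5--2, 0.75--2, 1--2 and the extended-upper-limit 0.5--2.5,
#' 0.75--2.5, 1--2.5). `extended = TRUE` appends two documented variants:
#' the cyclodextrin band as registered (2--25) and the miglustat band with
#' an explicit upper limit (12--60).
#'
#' @param extended Also return the variant age bands.
#' @return A list of [inclusion_criterion()] objects.
#' @export
criteria_catalog <- function(extended = FALSE) {
  out <- list(
    inclusion_criterion("miglustat_gt12", "age_band", 12, Inf, TRUE),
    inclusion_criterion("arimoclomol_2_18", "age_band", 2, 18, TRUE),
    inclusion_criterion("cyclodextrin_4_21", "age_band", 4, 21, TRUE),
    inclusion_criterion("asis_0.5_2", "asis_band", 0.5, 2),
    inclusion_criterion("asis_0.75_2", "asis_band", 0.75, 2),
    inclusion_criterion("asis_1_2", "asis_band", 1, 2),
    inclusion_criterion("asis_0.5_2.5", "asis_band", 0.5, 2.5),
    inclusion_criterion("asis_0.75_2.5", "asis_band", 0.75, 2.5),
    inclusion_criterion("asis_1_2.5", "asis_band", 1, 2.5)
  )
  if (extended) {
    out <- c(out, list(
      inclusion_criterion("cyclodextrin_2_25", "age_band", 2, 25, TRUE),
      inclusion_criterion("miglustat_12_60", "age_band", 12, 60, TRUE)
    ))
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# first-visit eligibility flags for one criterion
eligible_flags <- function(fv, criterion) {
  stopifnot(inherits(criterion, "inclusion_criterion"))
  val <- switch(criterion$kind, age_band = fv$age_years, asis_band = fv$asis)
  ok <- val >= criterion$lower & val <= criterion$upper
  if (criterion$require_signs) ok <- ok & fv$severity > 0
  ok
}

#' Evaluate an inclusion criterion on a cohort
#'
#' Eligibility is decided from each patient's first visit. Percentages are
#' over the full cohort (and within seizure / non-seizure groups), rounded
#' half-up to one decimal.
#'
#' @param cohort A cohort data.frame.
#' @param criterion An [inclusion_criterion()].
#' @param exclude Domains excluded from the severity total.
#' @return A list of class `eligibility_report`: `criterion`, `eligible`
#'   (per-patient data.frame), `percent_included`,
#'   `percent_included_seizure`, `percent_included_nonseizure`.
#' @export
evaluate_criterion <- function(cohort, criterion, exclude = character()) {
  fv <- first_visits(asis_scores(cohort, exclude = exclude))
  if (nrow(fv) == 0L) stop("empty cohort", call. = FALSE)
  seiz <- patient_table(cohort)$seizure_group
  ok <- eligible_flags(fv, criterion)
  pct <- function(flags) {
    if (length(flags) == 0L) return(NA_real_)
    round_half_up(100 * sum(flags) / length(flags), 1L)
  }
  structure(list(
    criterion = criterion,
    eligible = data.frame(patient_id = fv$patient_id, eligible = ok,
                          seizure_group = seiz, stringsAsFactors = FALSE),
    percent_included = pct(ok),
    percent_included_seizure = pct(ok[seiz]),
    percent_included_nonseizure = pct(ok[!seiz])
  ), class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cr <- x$criterion
  cat(sprintf("%s [%s %s-%s%s]: %.1f%% included (seizure %.1f%%, non-seizure %.1f%%)\n",
              cr$name, cr$kind, format(cr$lower), format(cr$upper),
              if (cr$require_signs) ", signs required" else "",
              x$percent_included, x$percent_included_seizure,
              x$percent_included_nonseizure))
  invisible(x)
}

#' Eligibility table over many criteria
#'
#' @param cohort A cohort data.frame.
#' @param criteria List of criteria (default: the built-in catalogue).
#' @param exclude Domains excluded from the severity total.
#' @return A data.frame with one row per criterion and the three inclusion
#'   percentages.
#' @export
eligibility_table <- function(cohort, criteria = criteria_catalog(),
                              exclude = character()) {
  out <- do.call(rbind, lapply(criteria, function(cr) {
    r <- evaluate_criterion(cohort, cr, exclude = exclude)
    data.frame(
      criterion = cr$name, kind = cr$kind, lower = cr$lower, upper = cr$upper,
      percent_included = r$percent_included,
      percent_included_seizure = r$percent_included_seizure,
      percent_included_nonseizure = r$percent_included_nonseizure,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Cross-tabulate two inclusion criteria
#'
#' Compares who an age-defined and an ASIS-defined trial would each
#' recruit: the percentage of the cohort included by both, excluded by
#' both, and included by exactly one.
#'
#' @param cohort A cohort data.frame.
#' @param criterion_a,criterion_b Two [inclusion_criterion()] objects.
#' @param exclude Domains excluded from the severity total.
#' @return A data.frame with `pct_both_included`, `pct_both_excluded`,
#'   `pct_a_only`, `pct_b_only` (half-up, one decimal; sum 100 up to
#'   rounding).
#' @export
cross_tabulate <- function(cohort, criterion_a, criterion_b,
                           exclude = character()) {
  fv <- first_visits(asis_scores(cohort, exclude = exclude))
  if (nrow(fv) == 0L) stop("empty cohort", call. = FALSE)
  a <- eligible_flags(fv, criterion_a)
  b <- eligible_flags(fv, criterion_b)
  n <- nrow(fv)
  data.frame(
    criterion_a = criterion_a$name, criterion_b = criterion_b$name,
    pct_both_included = round_half_up(100 * sum(a & b) / n, 1L),
    pct_both_excluded = round_half_up(100 * sum(!a & !b) / n, 1L),
    pct_a_only = round_half_up(100 * sum(a & !b) / n, 1L),
    pct_b_only = round_half_up(100 * sum(!a & b) / n, 1L),
    stringsAsFactors = FALSE
  )
}
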