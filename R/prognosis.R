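#' Reference ASIS for a patient's predicted trajectory
#'
#' The prognostic model predicts future severity as a straight line
#' through the origin with slope equal to a reference ASIS: either the
#' first-visit ASIS (`mode = "first"`) or the unweighted mean of all
#' per-visit ASIS values (`mode = "mean"`).
#'
#' @param patient A cohort data.frame subset for one patient (>= 1 visit),
#'   already scored by [asis_scores()] or raw (it is scored if needed).
#' @param mode `"first"` or `"mean"`.
#' @param exclude Domains excluded from the severity total.
#' @return The reference ASIS (severity units per year).
#' @export
asis_reference <- function(patient, mode = c("first", "mean"),
                           exclude = character()) {
  mode <- match.arg(mode)
  if (is.null(patient$asis)) patient <- asis_scores(patient, exclude = exclude)
  patient <- patient[order(patient$age_years), , drop = FALSE]
  switch(mode, first = patient$asis[1L], mean = mean(patient$asis))
}

#' Predict severity from a reference ASIS
#'
#' @param asis_ref Reference ASIS (severity units per year).
#' @param age Decimal age(s) in years, > 0.
#' @return Predicted severity `asis_ref * age` (through-origin line).
#' @export
predict_severity <- function(asis_ref, age) {
  if (any(age <= 0)) stop("age must be > 0", call. = FALSE)
  asis_ref * age
}

#' Per-patient maximum absolute deviation from the predicted trajectory
#'
#' The goodness-of-fit statistic for ASIS-based prognosis: the maximum
#' over a patient's visits of |observed severity - predicted severity|,
#' in severity units. With `mode = "first"` the first visit deviates by 0
#' by construction, so the maximum is attained later.
#'
#' @param patient One patient's visits (>= 2).
#' @param mode `"first"` or `"mean"` reference ASIS.
#' @param exclude Domains excluded from the severity total.
#' @return The patient's MAD (>= 0).
#' @export
patient_mad <- function(patient, mode = c("first", "mean"),
                        exclude = character()) {
  mode <- match.arg(mode)
  if (is.null(patient$asis)) patient <- asis_scores(patient, exclude = exclude)
  if (nrow(patient) < 2L) {
    stop("MAD needs >= 2 visits", call. = FALSE)
  }
  ref <- asis_reference(patient, mode)
  max(abs(patient$severity - predict_severity(ref, patient$age_years)))
}

# internal: per-patient MAD table for a whole cohort
cohort_mads <- function(cohort, mode, exclude = character()) {
  scored <- asis_scores(cohort, exclude = exclude)
  sp <- split(scored, scored$patient_id)
  out <- do.call(rbind, lapply(sp, function(p) {
    data.frame(
      patient_id = p$patient_id[1L],
      mad = patient_mad(p, mode),
      seizure_group = any(p$seizure_observed),
      span_years = max(p$age_years) - min(p$age_years),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Cohort MAD summaries by reference mode and seizure group
#'
#' Summarises per-patient MADs with median and quartiles, per reference
#' mode and (optionally) per seizure group, and attaches
#' Wilcoxon-Mann-Whitney (location) and Ansari-Bradley (dispersion)
#' comparisons: first vs mean within each stratum, and seizure vs
#' non-seizure within each mode.
#'
#' @param cohort A cohort data.frame.
#' @param modes Reference modes to evaluate.
#' @param stratify_by_seizure Split by seizure group.
#' @param exclude Domains excluded from the severity total.
#' @return A list with `summary` (data.frame: `mode`, `group`, `n`,
#'   `median`, `q1`, `q3`), `mads` (per-patient values) and `tests`
#'   (pairwise comparisons). Groups with < 2 patients are dropped with a
#'   warning.
#' @export
group_mad_summary <- function(cohort, modes = c("first", "mean"),
                              stratify_by_seizure = FALSE,
                              exclude = character()) {
  mads <- do.call(rbind, lapply(modes, function(m) {
    cbind(mode = m, cohort_mads(cohort, m, exclude = exclude))
  }))
  mads$group <- if (stratify_by_seizure) {
    ifelse(mads$seizure_group, "seizure", "non_seizure")
  } else "all"
  rows <- list(); tests <- list()
  for (m in modes) for (g in unique(mads$group)) {
    v <- mads$mad[mads$mode == m & mads$group == g]
    if (length(v) < 2L) {
      warning("group ", g, " (mode ", m, ") has < 2 patients; omitted",
              call. = FALSE)
      next
    }
    rows[[paste(m, g)]] <- cbind(data.frame(mode = m, group = g),
                                 cohort_summary(v))
  }
  if (length(modes) == 2L) {
    for (g in unique(mads$group)) {
      v1 <- mads$mad[mads$mode == modes[1L] & mads$group == g]
      v2 <- mads$mad[mads$mode == modes[2L] & mads$group == g]
      if (length(v1) >= 2L && length(v2) >= 2L) {
        tt <- compare_groups(v1, v2)
        tt$comparison <- paste0(modes[1L], "_vs_", modes[2L], " (", g, ")")
        tests[[paste("mode", g)]] <- tt
      }
    }
  }
  if (stratify_by_seizure) {
    for (m in modes) {
      vs <- mads$mad[mads$mode == m & mads$group == "seizure"]
      vn <- mads$mad[mads$mode == m & mads$group == "non_seizure"]
      if (length(vs) >= 2L && length(vn) >= 2L) {
        tt <- compare_groups(vs, vn)
        tt$comparison <- paste0("seizure_vs_non_seizure (", m, ")")
        tests[[paste("seiz", m)]] <- tt
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary,
       mads = mads[, c("mode", "group", "patient_id", "mad", "span_years")],
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' MAD summaries by follow-up window
#'
#' Each patient contributes once, assigned by total follow-up span (last
#' age minus first age) to one of the right-closed windows (0,2\], (2,4\],
#' (4,6\] years; spans beyond 6 years fall into the last window with a
#' warning.
#'
#' @param cohort A cohort data.frame.
#' @param mode Reference ASIS mode.
#' @param exclude Domains excluded from the severity total.
#' @return A data.frame with `window`, `n`, `median`, `q1`, `q3`; window
#'   counts sum to the cohort size.
#' @export
windowed_mad <- function(cohort, mode = c("first", "mean"),
                         exclude = character()) {
  mode <- match.arg(mode)
  mads <- cohort_mads(cohort, mode, exclude = exclude)
  if (any(mads$span_years > 6)) {
    warning(sum(mads$span_years > 6),
            " patient(s) with follow-up > 6 years assigned to the 4-6 window",
            call. = FALSE)
  }
  win <- cut(pmin(mads$span_years, 6), breaks = c(0, 2, 4, 6), right = TRUE,
             labels = c("0-2", "2-4", "4-6"))
  out <- do.call(rbind, lapply(levels(win), function(w) {
    v <- mads$mad[win == w]
    if (length(v) == 0L) {
      return(data.frame(window = w, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_))
    }
    cbind(data.frame(window = w), cohort_summary(v))
  }))
  rownames(out) <- NULL
  out
}
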