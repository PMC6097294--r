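#' Per-visit ASIS scores
#'
#' The annual severity increment score (ASIS) of a visit is the composite
#' severity total divided by the patient's decimal age at that visit, in
#' severity units per year. It indexes the average annual rate of disease
#' progression up to that visit.
#'
#' @param cohort A cohort data.frame (see [cohort-format]).
#' @param exclude Domains to leave out of the severity total.
#' @return The cohort with `severity` and `asis` columns appended.
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1))
#' head(asis_scores(coh)[, c("patient_id", "age_years", "severity", "asis")])
#' @export
asis_scores <- function(cohort, exclude = character()) {
  cohort <- validate_cohort(cohort)
  cohort$severity <- total_severity(cohort, exclude = exclude)
  cohort$asis <- cohort$severity / cohort$age_years
  cohort
}

#' Per-patient ASIS rate of change
#'
#' Fits, for each patient with at least two visits, an ordinary
#' least-squares line of per-visit ASIS on time since the patient's first
#' visit. A slope near zero means the patient's annual progression rate is
#' constant -- the property that makes ASIS usable for stratification.
#'
#' @param cohort A cohort data.frame.
#' @param exclude Domains excluded from the severity total.
#' @return A data.frame with one row per patient: `patient_id`, `n_visits`,
#'   `slope` (ASIS units per year^2), `intercept`, `seizure_group`.
#' @export
asis_slopes <- function(cohort, exclude = character()) {
  scored <- asis_scores(cohort, exclude = exclude)
  sp <- split(scored, scored$patient_id)
  out <- do.call(rbind, lapply(sp, function(p) {
    if (nrow(p) < 2L || length(unique(p$age_years)) < 2L) {
      stop("patient ", p$patient_id[1L],
           ": ASIS slope needs >= 2 visits at distinct ages", call. = FALSE)
    }
    t <- p$age_years - min(p$age_years)
    fit <- stats::lm.fit(cbind(1, t), p$asis)
    data.frame(
      patient_id = p$patient_id[1L],
      n_visits = nrow(p),
      slope = unname(fit$coefficients[2L]),
      intercept = unname(fit$coefficients[1L]),
      seizure_group = any(p$seizure_observed),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Classify patients as ASIS-stable by the Tukey whisker rule
#'
#' A patient is "stable" when their ASIS slope lies within the classic
#' Tukey box-plot whiskers of the cohort slope distribution,
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\]; slopes outside the whiskers are
#' progression-rate outliers.
#'
#' @param slopes A data.frame from [asis_slopes()] (any data.frame with a
#'   `slope` column works).
#' @return `slopes` with a logical `stable` column appended.
#' @export
classify_stability <- function(slopes) {
  s <- slopes$slope
  if (length(s) < 4L || anyNA(s)) {
    stop("stability classification needs >= 4 defined slopes", call. = FALSE)
  }
  q <- stats::quantile(s, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  slopes$stable <- s >= q[1L] - 1.5 * iqr & s <= q[2L] + 1.5 * iqr
  slopes
}

#' Median and quartiles of a sample
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention used for every quartile
#' summary in this package.
#'
#' @param values Non-empty numeric vector.
#' @param by Optional grouping factor (e.g. seizure group); when given, one
#'   summary per group is returned.
#' @return A data.frame with columns `group` (absent when `by` is NULL),
#'   `n`, `median`, `q1`, `q3`.
#' @export
cohort_summary <- function(values, by = NULL) {
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  one <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(n = length(v), median = q[2L], q1 = q[1L], q3 = q[3L])
  }
  if (is.null(by)) return(one(values))
  sp <- split(values, by)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE), one(sp[[g]]))
  }))
  rownames(out) <- NULL
  out
}

#' Silverman bandwidth for a Gaussian kernel
#'
#' h = 0.9 min(sd, IQR/1.34) n^(-1/5). Degenerate samples (zero spread)
#' are rejected.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Bandwidth in data units.
#' @export
silverman_bandwidth <- function(values) {
  if (length(unique(values)) < 2L) {
    stop("bandwidth undefined for degenerate data", call. = FALSE)
  }
  s <- stats::sd(values)
  iqr <- stats::IQR(values, type = 7)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  0.9 * spread * length(values)^(-1 / 5)
}

#' Gaussian kernel density estimate with Silverman's bandwidth
#'
#' @param values Numeric vector with at least two distinct values.
#' @param by Optional grouping factor; one density per group.
#' @param n Number of grid points.
#' @return For ungrouped input, a data.frame with columns `x` (grid) and
#'   `density`; with `by`, an additional `group` column. The trapezoid
#'   integral of each density over its grid is 1 within 1%.
#' @export
density_estimate <- function(values, by = NULL, n = 512L) {
  one <- function(v) {
    d <- stats::density(v, bw = silverman_bandwidth(v), kernel = "gaussian",
                        n = n)
    data.frame(x = d$x, density = d$y)
  }
  if (is.null(by)) return(one(values))
  sp <- split(values, by)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE), one(sp[[g]]))
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample location and dispersion comparison
#'
#' Wilcoxon-Mann-Whitney for location and Ansari-Bradley for dispersion,
#' the pair of nonparametric tests used throughout the ASIS analyses (e.g.
#' seizure vs non-seizure slope distributions, first- vs mean-ASIS MAD).
#'
#' @param x,y Numeric samples.
#' @return A data.frame with the two statistics and p-values.
#' @export
compare_groups <- function(x, y) {
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  a <- suppressWarnings(stats::ansari.test(x, y, exact = FALSE))
  data.frame(
    test = c("wilcoxon_mann_whitney", "ansari_bradley"),
    statistic = c(unname(w$statistic), unname(a$statistic)),
    p_value = c(w$p.value, a$p.value),
    stringsAsFactors = FALSE
  )
}
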