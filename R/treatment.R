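#' Fit the on-treatment ASIS mixed model
#'
#' Estimates the average annual change in ASIS while on therapy with a
#' linear mixed-effects model: asis ~ time on treatment, with a random
#' intercept per patient absorbing between-patient baseline differences.
#' The fixed slope is the average ASIS change per treatment year; its
#' p-value is a Wald test (normal approximation to the t statistic).
#'
#' @param observations A data.frame with columns `patient_id`,
#'   `time_on_treatment` (years since treatment start, >= 0; baseline
#'   visits enter at 0) and `asis`.
#' @param method `"REML"` (default) or `"ML"`.
#' @return An object of class `treatment_fit`: `fixed_intercept`,
#'   `fixed_slope`, `random_intercept_sd`, `residual_sd`, `slope_se`,
#'   `slope_p_value`, `percent_annual_change`, `n_patients`, `n_obs`,
#'   `singular` (TRUE when the random-intercept variance collapsed to the
#'   boundary, e.g. one observation per patient), and the underlying
#'   `lme4` fit as `model`.
#' @examples
#' obs <- generate_treatment_series(treatment_config(seed = 2))
#' fit <- fit_treatment_model(obs)
#' fit$fixed_slope
#' @export
fit_treatment_model <- function(observations, method = c("REML", "ML")) {
  method <- match.arg(method)
  need <- c("patient_id", "time_on_treatment", "asis")
  missing <- setdiff(need, names(observations))
  if (length(missing) > 0L) {
    stop("observations missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(observations$time_on_treatment < 0)) {
    stop("time_on_treatment must be >= 0", call. = FALSE)
  }
  if (length(unique(observations$patient_id)) < 2L) {
    stop("need >= 2 patients", call. = FALSE)
  }
  if (stats::sd(observations$time_on_treatment) == 0) {
    stop("degenerate design: all observation times equal", call. = FALSE)
  }
  if (max(table(observations$patient_id)) < 2L) {
    # one observation per patient: the random intercept is not identifiable
    # and the model degrades to ordinary regression
    warning("one observation per patient; random-intercept variance is at ",
            "the boundary and the fit reduces to ordinary regression",
            call. = FALSE)
    fit <- stats::lm(asis ~ time_on_treatment, data = observations)
    ols <- summary(fit)
    co <- ols$coefficients
    singular <- TRUE
    ri_sd <- 0
    resid_sd <- ols$sigma
  } else {
    fit <- suppressMessages(lme4::lmer(
      asis ~ time_on_treatment + (1 | patient_id),
      data = observations, REML = (method == "REML")
    ))
    singular <- lme4::isSingular(fit)
    if (singular) {
      warning("random-intercept variance at the boundary; ",
              "fit degrades to ordinary regression", call. = FALSE)
    }
    co <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)
    ri_sd <- attr(vc$patient_id, "stddev")[["(Intercept)"]]
    resid_sd <- attr(vc, "sc")
  }
  slope <- co["time_on_treatment", "Estimate"]
  se <- co["time_on_treatment", "Std. Error"]
  intercept <- co["(Intercept)", "Estimate"]
  out <- list(
    fixed_intercept = intercept,
    fixed_slope = slope,
    random_intercept_sd = ri_sd,
    residual_sd = resid_sd,
    slope_se = se,
    slope_p_value = 2 * stats::pnorm(-abs(slope / se)),
    percent_annual_change = if (intercept != 0) 100 * slope / intercept
                            else NA_real_,
    n_patients = length(unique(observations$patient_id)),
    n_obs = nrow(observations),
    method = method,
    singular = singular,
    model = fit
  )
  class(out) <- "treatment_fit"
  out
}

#' Percent annual ASIS change of a treatment fit
#'
#' Expresses the fixed slope relative to the model's fitted baseline:
#' 100 * fixed_slope / fixed_intercept, sign carried (negative =
#' improvement, i.e. slowing of progression).
#'
#' @param fit A `treatment_fit`.
#' @return Percent change in ASIS per treatment year.
#' @export
percent_annual_change <- function(fit) {
  stopifnot(inherits(fit, "treatment_fit"))
  if (fit$fixed_intercept == 0) {
    stop("fitted baseline is zero; percent change undefined", call. = FALSE)
  }
  100 * fit$fixed_slope / fit$fixed_intercept
}

#' @export
print.treatment_fit <- function(x, ...) {
  cat("On-treatment ASIS mixed model (", x$method, ", ",
      x$n_patients, " patients, ", x$n_obs, " observations)\n", sep = "")
  cat(sprintf("  fixed slope: %+.4f ASIS units/year (SE %.4f, Wald p = %.3g)\n",
              x$fixed_slope, x$slope_se, x$slope_p_value))
  cat(sprintf("  fitted baseline: %.4f; percent annual change: %+.1f%%\n",
              x$fixed_intercept, x$percent_annual_change))
  cat(sprintf("  random intercept sd: %.4f; residual sd: %.4f%s\n",
              x$random_intercept_sd, x$residual_sd,
              if (x$singular) " (singular fit)" else ""))
  invisible(x)
}
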