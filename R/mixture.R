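#' Latent-class mixture regression of severity on age
#'
#' Fits a K-component Gaussian mixture of linear regressions
#' y = a_k + b_k x + e, e ~ N(0, sigma^2), by expectation-maximisation,
#' modelling K latent progression classes (lines in the age-severity
#' plane). The residual standard deviation is shared across classes
#' (homoscedastic) unless `common_sd = FALSE`. Classes are relabelled in
#' ascending slope order so labels are canonical.
#'
#' Initialisation seeds the class slopes at quantiles of the per-point
#' severity/age ratios (a natural scale for through-origin-like progression
#' lines); `n_restarts` jittered restarts are run and the best
#' log-likelihood kept. The observed-data log-likelihood is non-decreasing
#' across EM iterations.
#'
#' @param age,severity Numeric vectors of equal length (one point per
#'   patient, typically at first visit).
#' @param k Number of latent classes (>= 1).
#' @param seed Integer seed controlling initialisation jitter.
#' @param intercept Fit free intercepts (default) or force lines through
#'   the origin.
#' @param common_sd Share one residual sd across classes.
#' @param n_restarts Number of jittered EM restarts.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations per restart.
#' @return An object of class `subgroup_model`: list with `k`, `slopes`,
#'   `intercepts`, `weights`, `residual_sd` (per class if
#'   `common_sd = FALSE`), `loglik`, `loglik_trace`, `converged`, `n_iter`,
#'   `seed`.
#' @examples
#' set.seed(1)
#' x <- runif(40, 2, 20)
#' y <- c(0.5 * x[1:20], 3 * x[21:40]) + rnorm(40, 0, 0.1)
#' m <- fit_latent_class_lines(x, y, k = 2, seed = 1)
#' m$slopes
#' @export
fit_latent_class_lines <- function(age, severity, k, seed = 1L,
                                   intercept = TRUE, common_sd = TRUE,
                                   n_restarts = 10L, tol = 1e-8,
                                   max_iter = 500L) {
  stopifnot(length(age) == length(severity))
  n <- length(age)
  if (n == 0L) stop("no data points", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (n < 2L * k) {
    stop("need at least 2 points per class (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }

  if (k == 1L) {
    X <- if (intercept) cbind(1, age) else cbind(age)
    fit <- stats::lm.fit(X, severity)
    res <- fit$residuals
    sd0 <- sqrt(sum(res^2) / n)
    co <- fit$coefficients
    out <- list(
      k = 1L,
      slopes = unname(if (intercept) co[2L] else co[1L]),
      intercepts = if (intercept) unname(co[1L]) else 0,
      weights = 1,
      residual_sd = sd0,
      loglik = sum(stats::dnorm(res, 0, max(sd0, 1e-12), log = TRUE)),
      loglik_trace = NULL, converged = TRUE, n_iter = 0L, seed = seed
    )
    class(out) <- "subgroup_model"
    return(out)
  }

  best <- NULL
  ratio_q <- stats::quantile(severity / age, probs = (seq_len(k) - 0.5) / k,
                             names = FALSE, type = 7)
  rng <- local({ set.seed(as.integer(seed)); NULL })
  set.seed(as.integer(seed))
  for (r in seq_len(max(1L, as.integer(n_restarts)))) {
    jitter_sd <- if (r == 1L) 0 else 0.15 * max(stats::sd(severity / age), 1e-6)
    b0 <- sort(ratio_q + stats::rnorm(k, 0, jitter_sd))
    a0 <- rep(0, k)
    s0 <- rep(max(stats::sd(severity - b0[ceiling(k / 2)] * age), 1e-3), k)
    fit <- em_lines(age, severity, k, b0, a0, s0, intercept, common_sd,
                    tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$slopes)
  out <- list(
    k = k,
    slopes = best$slopes[ord],
    intercepts = best$intercepts[ord],
    weights = best$weights[ord],
    residual_sd = if (common_sd) best$sd[1L] else best$sd[ord],
    loglik = best$loglik,
    loglik_trace = best$trace,
    converged = best$converged,
    n_iter = best$n_iter,
    seed = as.integer(seed)
  )
  if (!out$converged) {
    warning("EM did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  class(out) <- "subgroup_model"
  out
}

# one EM run; returns unsorted parameters
em_lines <- function(x, y, k, b, a, s, intercept, common_sd, tol, max_iter) {
  n <- length(x)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E step: responsibilities from current lines
    dens <- vapply(seq_len(k), function(j) {
      stats::dnorm(y, a[j] + b[j] * x, max(s[j], 1e-10)) * w[j]
    }, numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < 1e-300] <- 1e-300
    gamma <- dens / rowsum_d
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M step: weighted least squares per class
    for (j in seq_len(k)) {
      g <- gamma[, j]
      sw <- sum(g)
      if (sw < 1e-8) next  # empty class keeps its parameters
      if (intercept) {
        xb <- sum(g * x) / sw
        yb <- sum(g * y) / sw
        sxx <- sum(g * (x - xb)^2)
        b[j] <- if (sxx > 0) sum(g * (x - xb) * (y - yb)) / sxx else b[j]
        a[j] <- yb - b[j] * xb
      } else {
        sxx <- sum(g * x^2)
        b[j] <- if (sxx > 0) sum(g * x * y) / sxx else b[j]
        a[j] <- 0
      }
    }
    resid2 <- vapply(seq_len(k), function(j) (y - a[j] - b[j] * x)^2,
                     numeric(n))
    if (common_sd) {
      s[] <- sqrt(sum(gamma * resid2) / n)
    } else {
      s <- sqrt(colSums(gamma * resid2) / pmax(colSums(gamma), 1e-8))
    }
    s <- pmax(s, 1e-6)
    w <- colSums(gamma) / n
  }
  list(slopes = b, intercepts = a, weights = w, sd = s, loglik = ll_old,
       trace = trace, converged = converged, n_iter = it)
}

#' @export
print.subgroup_model <- function(x, ...) {
  cat("Latent-class mixture of", x$k, "regression lines",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("log-likelihood:", format(x$loglik), "\n")
  tab <- data.frame(class = seq_len(x$k), slope = x$slopes,
                    intercept = x$intercepts, weight = x$weights)
  print(tab, row.names = FALSE, digits = 4)
  cat("residual sd:", format(x$residual_sd, digits = 4), "\n")
  invisible(x)
}

#' Assign points to the nearest progression line
#'
#' Each (age, severity) point is assigned to the class whose line passes
#' closest in severity (vertical distance) at that age; ties break toward
#' the lower class index.
#'
#' @param model A `subgroup_model`.
#' @param age,severity Numeric vectors.
#' @return Integer class labels in 1..k.
#' @export
assign_subgroup <- function(model, age, severity) {
  stopifnot(inherits(model, "subgroup_model"))
  d <- vapply(seq_len(model$k), function(j) {
    abs(severity - (model$intercepts[j] + model$slopes[j] * age))
  }, numeric(length(age)))
  d <- matrix(d, nrow = length(age))
  apply(d, 1L, which.min)  # which.min takes the first (lowest) index on ties
}

#' Subgroup labels at first and last visit
#'
#' @param cohort A cohort data.frame.
#' @param model A fitted `subgroup_model`.
#' @param exclude Domains excluded from the severity total.
#' @return One row per patient: `patient_id`, `label_first`, `label_last`,
#'   `shift` = |label_last - label_first|.
#' @export
subgroup_assignments <- function(cohort, model, exclude = character()) {
  scored <- asis_scores(cohort, exclude = exclude)
  sp <- split(scored, scored$patient_id)
  out <- do.call(rbind, lapply(sp, function(p) {
    p <- p[order(p$age_years), , drop = FALSE]
    lf <- assign_subgroup(model, p$age_years[1L], p$severity[1L])
    ll <- assign_subgroup(model, p$age_years[nrow(p)], p$severity[nrow(p)])
    data.frame(patient_id = p$patient_id[1L], label_first = lf,
               label_last = ll, shift = abs(ll - lf),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Histogram of classification-category shifts
#'
#' Counts patients by how many classes their assignment moved between
#' first and last visit; a cohort with stable progression rates
#' concentrates at shift 0, and shifts beyond one adjacent class should be
#' rare.
#'
#' @param assignments Output of [subgroup_assignments()].
#' @param k Number of classes (defaults to the largest label seen).
#' @return A data.frame with `shift` (0..k-1) and `n`; `sum(n)` equals the
#'   number of patients.
#' @export
category_shift_table <- function(assignments,
                                 k = max(assignments$label_first,
                                         assignments$label_last)) {
  shifts <- factor(assignments$shift, levels = 0:(k - 1L))
  data.frame(shift = 0:(k - 1L), n = as.integer(table(shifts)))
}
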