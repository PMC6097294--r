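#' Spearman rank correlation
#'
#' Tie-aware Spearman correlation: the Pearson correlation of
#' average-ranked values, via `stats::cor(method = "spearman")`.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Spearman p-value (t approximation)
#'
#' @param rho Spearman correlation.
#' @param n Number of observations.
#' @return Two-sided p-value from the t approximation with n-2 df.
#' @export
spearman_p <- function(rho, n) {
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Exhaustive subset scan of major subdomains against total severity
#'
#' For every subset of `m` of the 8 major domains (8 singles, 28 pairs or
#' 56 triads), correlates the subset score sum with the full composite
#' total (`rho_included`) and with the total computed excluding the
#' subset's own scores (`rho_excluded`). This quantifies how well a reduced
#' clinical panel tracks the full scale. One row per patient (first visit)
#' is used unless `all_visits = TRUE`.
#'
#' @param cohort A cohort data.frame (>= 4 patients).
#' @param m Subset size: 1, 2 or 3.
#' @param all_visits Pool every visit instead of first visits only.
#' @return A data.frame with `subset` (domain names joined by `+`),
#'   `rho_included`, `rho_excluded`, `p_included`, `p_excluded`, `n`.
#' @export
subset_scan <- function(cohort, m, all_visits = FALSE) {
  if (!m %in% 1:3) stop("m must be 1, 2 or 3", call. = FALSE)
  rows <- if (all_visits) validate_cohort(cohort) else first_visits(validate_cohort(cohort))
  if (nrow(rows) < 4L) stop("need >= 4 observations", call. = FALSE)
  total <- total_severity(rows)
  combos <- utils::combn(major_domains(), m, simplify = FALSE)
  # a constant subset (or constant remainder) has no defined correlation;
  # reported as NA rather than aborting the whole scan
  safe_rho <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else spearman_rho(a, b)
  }
  out <- do.call(rbind, lapply(combos, function(doms) {
    sub_sum <- rowSums(rows[, doms, drop = FALSE])
    ri <- safe_rho(sub_sum, total)
    re <- safe_rho(sub_sum, total - sub_sum)
    data.frame(
      subset = paste(doms, collapse = "+"),
      rho_included = ri, rho_excluded = re,
      p_included = spearman_p(ri, nrow(rows)),
      p_excluded = spearman_p(re, nrow(rows)),
      n = nrow(rows), stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Correlation of an arbitrary domain panel with total severity
#'
#' @param cohort A cohort data.frame.
#' @param panel Non-empty character vector of domain names (major or
#'   minor), e.g. the five quality-of-life domains ranked most important by
#'   clinicians and families.
#' @param exclude_panel Correlate against the total minus the panel's own
#'   scores instead of the full total.
#' @param all_visits Pool every visit instead of first visits only.
#' @return Spearman correlation.
#' @export
panel_correlation <- function(cohort, panel, exclude_panel = FALSE,
                              all_visits = FALSE) {
  panel <- check_excluded(panel)  # same domain-name validation
  if (length(panel) == 0L) stop("empty panel", call. = FALSE)
  rows <- if (all_visits) validate_cohort(cohort) else first_visits(validate_cohort(cohort))
  sub_sum <- rowSums(rows[, panel, drop = FALSE])
  total <- total_severity(rows)
  if (exclude_panel) total <- total - sub_sum
  spearman_rho(sub_sum, total)
}

#' Pairwise Spearman correlations between the major subdomains
#'
#' @param cohort A cohort data.frame.
#' @param all_visits Pool every visit instead of first visits only.
#' @return An 8 x 8 symmetric correlation matrix (unit diagonal).
#' @export
major_domain_correlations <- function(cohort, all_visits = FALSE) {
  rows <- if (all_visits) validate_cohort(cohort) else first_visits(validate_cohort(cohort))
  stats::cor(rows[, major_domains()], method = "spearman")
}

#' Aggregate questionnaire importance rankings
#'
#' Each respondent ranks `n_items` symptoms/domains from 1 (most impact)
#' upward. Per-item ranks are summed across respondents and items placed in
#' ascending order of rank sum; the smallest sum gets final position 1.
#' Ties share the lower position (dense ranking: tied items get the same
#' position and the next distinct sum gets the next position).
#'
#' @param responses A respondent x item matrix or data.frame of integer
#'   ranks; each respondent's ranks must lie in 1..n_items.
#' @param group Optional respondent-group label stored on the result.
#' @return A data.frame with `item`, `rank_sum`, `position`, sorted by
#'   position; attribute `respondent_group` carries `group`.
#' @export
aggregate_ranks <- function(responses, group = NA_character_) {
  responses <- as.matrix(responses)
  n_items <- ncol(responses)
  if (is.null(colnames(responses))) {
    colnames(responses) <- paste0("item_", seq_len(n_items))
  }
  bad <- !(responses %in% seq_len(n_items)) | is.na(responses)
  if (any(bad)) {
    stop("ranks must be integers in 1..", n_items, "; ",
         sum(bad), " value(s) out of range", call. = FALSE)
  }
  sums <- colSums(responses)
  position <- match(sums, sort(unique(sums)))  # dense ranking
  out <- data.frame(item = colnames(responses), rank_sum = unname(sums),
                    position = position, stringsAsFactors = FALSE)
  out <- out[order(out$position, out$item), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "respondent_group") <- group
  out
}
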