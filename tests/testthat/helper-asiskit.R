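# shared fixtures and independent oracles, built in code

# a visit table of n rows with every domain at 0
zero_visits <- function(n = 1L) {
  doms <- npc_domains()$domain
  out <- as.data.frame(matrix(0L, nrow = n, ncol = length(doms),
                              dimnames = list(NULL, doms)))
  out
}

# build a valid cohort from per-patient ages and severity totals;
# subdomain scores come from the deterministic allocator
make_cohort <- function(patients) {
  rows <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    seizure <- isTRUE(p$seizure)
    scores <- t(vapply(p$severity, function(s) {
      maxima <- domain_maxima_for_test(seizure)
      allocate_subdomains(s, maxima = maxima)
    }, integer(16L)))
    colnames(scores) <- npc_domains()$domain
    data.frame(
      patient_id = if (!is.null(p$id)) p$id else sprintf("X%02d", i),
      centre = "centre_1",
      age_years = p$ages,
      as.data.frame(scores),
      seizure_observed = seizure & scores[, "seizures"] > 0L,
      treatment_start_age = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  validate_cohort(do.call(rbind, rows))
}

domain_maxima_for_test <- function(seizure) {
  d <- npc_domains()
  m <- stats::setNames(d$max_score, d$domain)
  if (!seizure) m[["seizures"]] <- 0L
  m
}

# independent Spearman oracle: manual tie-averaged ranks, then the
# explicit Pearson sum formula (no calls into cor())
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# independent quartile/whisker oracle: quartiles by direct linear
# interpolation of sorted order statistics
brute_whisker_flags <- function(slopes) {
  qi <- function(v, p) {
    v <- sort(v); n <- length(v)
    h <- (n - 1) * p
    lo <- floor(h) + 1
    hi <- ceiling(h) + 1
    v[lo] + (h - floor(h)) * (v[hi] - v[lo])
  }
  q1 <- qi(slopes, 0.25); q3 <- qi(slopes, 0.75)
  iqr <- q3 - q1
  slopes >= q1 - 1.5 * iqr & slopes <= q3 + 1.5 * iqr
}
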