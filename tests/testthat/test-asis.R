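test_that("ASIS is severity divided by age", {
  coh <- make_cohort(list(
    list(ages = c(10, 16.5), severity = c(10L, 33L)),
    list(ages = c(5, 8), severity = c(0L, 0L))
  ))
  scored <- asis_scores(coh)
  expect_equal(scored$asis, scored$severity / scored$age_years)
  expect_equal(scored$asis[scored$age_years == 10], 1.0)
  expect_equal(scored$asis[scored$age_years == 16.5], 2.0)
  expect_true(all(scored$asis[scored$patient_id == "X02"] == 0))
})

test_that("ASIS slopes are the OLS fit on time since first visit", {
  # constant ASIS: slope exactly 0 (severity = r * age at every visit)
  coh1 <- make_cohort(list(list(ages = c(5, 10, 20), severity = c(10L, 20L, 40L))))
  s1 <- asis_slopes(coh1)
  expect_equal(s1$slope, 0)
  expect_equal(s1$intercept, 2)

  # two points: slope is the difference quotient
  coh2 <- make_cohort(list(list(ages = c(5, 10), severity = c(5L, 20L))))
  s2 <- asis_slopes(coh2)   # ASIS 1 then 2 over 5 years
  expect_equal(s2$slope, (2 - 1) / 5)

  # 5 visits with ASIS = 0.6 + 0.005 t exactly: closed-form OLS on a
  # noiseless line (ages chosen so severity = asis * age stays integral)
  ages <- c(10, 20, 30, 40, 50)
  t <- ages - 10
  asis_target <- 0.6 + 0.005 * t
  sev <- asis_target * ages   # 6, 13, 21, 30, 40
  expect_true(all(sev == round(sev)))
  coh3 <- make_cohort(list(list(ages = ages, severity = as.integer(sev))))
  s3 <- asis_slopes(coh3)
  expect_equal(s3$slope, 0.005, tolerance = 1e-12)
  expect_equal(s3$intercept, 0.6, tolerance = 1e-12)

  expect_error(asis_slopes(coh1[1L, , drop = FALSE]), ">= 2 visits")
})

test_that("ASIS and slopes scale linearly with severity", {
  coh <- make_cohort(list(
    list(ages = c(4, 6, 9), severity = c(4L, 7L, 12L)),
    list(ages = c(10, 12), severity = c(8L, 11L))
  ))
  doubled <- make_cohort(list(
    list(ages = c(4, 6, 9), severity = c(8L, 14L, 24L)),
    list(ages = c(10, 12), severity = c(16L, 22L))
  ))
  expect_equal(asis_scores(doubled)$asis, 2 * asis_scores(coh)$asis)
  expect_equal(asis_slopes(doubled)$slope, 2 * asis_slopes(coh)$slope)
})

test_that("Tukey whisker stability matches direct quartile enumeration", {
  # all slopes identical: IQR 0, everyone stable
  sl <- data.frame(slope = rep(0.02, 6))
  expect_true(all(classify_stability(sl)$stable))

  # a single extreme value is flagged
  sl <- data.frame(slope = c(rep(0, 7), 10))
  flags <- classify_stability(sl)$stable
  expect_equal(flags, c(rep(TRUE, 7), FALSE))
  expect_equal(flags, brute_whisker_flags(sl$slope))

  # property: agreement with the enumeration oracle on random cohorts,
  # and invariance to row order
  set.seed(9)
  for (i in 1:25) {
    s <- rnorm(sample(4:40, 1L)) + rt(1, df = 2)
    got <- classify_stability(data.frame(slope = s))$stable
    expect_equal(got, brute_whisker_flags(s))
    perm <- sample(length(s))
    expect_equal(classify_stability(data.frame(slope = s[perm]))$stable,
                 got[perm])
  }
  expect_error(classify_stability(data.frame(slope = c(0, 1, 2))), ">= 4")
})

test_that("cohort slopes on a near-constant-rate cohort are mostly stable", {
  coh <- generate_cohort(cohort_config(seed = 31))
  sl <- classify_stability(asis_slopes(coh))
  expect_gte(mean(sl$stable), 0.8)
})

test_that("cohort_summary uses linear-interpolation quartiles", {
  s <- cohort_summary(c(1, 2, 3))
  expect_equal(s$median, 2)
  expect_equal(s$q1, 1.5)
  expect_equal(s$q3, 2.5)
  s1 <- cohort_summary(7.3)
  expect_equal(c(s1$median, s1$q1, s1$q3), rep(7.3, 3))
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(cohort_summary(sym)$median, 0)
  expect_error(cohort_summary(numeric(0)), "empty")
  by <- cohort_summary(c(1, 2, 3, 10, 20, 30), by = rep(c("a", "b"), each = 3))
  expect_equal(by$median, c(2, 20))
})

test_that("density estimate uses Silverman's bandwidth and normalises", {
  set.seed(10)
  x <- rnorm(100)
  n <- length(x)
  h_formula <- 0.9 * min(sd(x), IQR(x) / 1.34) * n^(-1 / 5)
  expect_equal(silverman_bandwidth(x), h_formula, tolerance = 1e-12)
  expect_equal(silverman_bandwidth(x), bw.nrd0(x), tolerance = 1e-12)

  d <- density_estimate(x)
  integral <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_gte(integral, 0.99)
  expect_lte(integral, 1.01)

  # symmetric sample: density symmetric about 0 within tolerance
  xs <- c(x, -x)
  ds <- density_estimate(xs, n = 501L)
  expect_equal(ds$density, rev(ds$density), tolerance = 1e-3)

  expect_error(density_estimate(rep(1, 10)), "degenerate")
})

test_that("group comparisons report Wilcoxon and Ansari-Bradley p-values", {
  set.seed(2)
  out <- compare_groups(rnorm(20), rnorm(20, 2))
  expect_equal(out$test, c("wilcoxon_mann_whitney", "ansari_bradley"))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_lt(out$p_value[1L], 0.01)  # clear location shift
})
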