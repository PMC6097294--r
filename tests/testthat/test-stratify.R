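test_that("the built-in criteria catalogue matches the modelled trials", {
  cat_ <- criteria_catalog()
  expect_length(cat_, 9L)
  mig <- cat_[["miglustat_gt12"]]
  expect_equal(mig$lower, 12)
  expect_equal(mig$upper, Inf)
  expect_true(mig$require_signs)
  asis_crit <- Filter(function(cr) cr$kind == "asis_band", cat_)
  expect_length(asis_crit, 6L)
  expect_true(all(!vapply(asis_crit, `[[`, TRUE, "require_signs")))
  bands <- t(vapply(asis_crit, function(cr) c(cr$lower, cr$upper), numeric(2)))
  expect_true(all(apply(bands, 1, diff) > 0))
  # registered-variant bands available behind a flag
  ext <- criteria_catalog(extended = TRUE)
  expect_length(ext, 11L)
  expect_equal(ext[["cyclodextrin_2_25"]]$upper, 25)
  expect_error(inclusion_criterion("bad", "age_band", 5, 2), "lower > upper")
})

test_that("eligibility percentages follow the first-visit band rule", {
  # four patients with first-visit ASIS 0.3, 0.8, 1.5, 2.4
  coh <- make_cohort(list(
    list(ages = c(10, 12), severity = c(3L, 4L)),     # ASIS 0.3
    list(ages = c(10, 12), severity = c(8L, 10L)),    # ASIS 0.8
    list(ages = c(10, 12), severity = c(15L, 18L)),   # ASIS 1.5
    list(ages = c(10, 12), severity = c(24L, 29L))    # ASIS 2.4
  ))
  band <- inclusion_criterion("test", "asis_band", 0.5, 2)
  rep_ <- evaluate_criterion(coh, band)
  expect_equal(rep_$percent_included, 50.0)
  expect_equal(rep_$eligible$eligible, c(FALSE, TRUE, TRUE, FALSE))

  # all-covering and impossible bands
  expect_equal(evaluate_criterion(
    coh, inclusion_criterion("all", "asis_band", 0, Inf))$percent_included, 100)
  expect_equal(evaluate_criterion(
    coh, inclusion_criterion("none", "asis_band", 0, 0.1))$percent_included, 0)
})

test_that("positive ASIS lower bounds exclude severity-zero patients", {
  coh <- make_cohort(list(
    list(ages = c(5, 8), severity = c(0L, 0L)),
    list(ages = c(5, 8), severity = c(5L, 8L))
  ))
  band <- inclusion_criterion("b", "asis_band", 0.5, 2)
  expect_equal(evaluate_criterion(coh, band)$eligible$eligible, c(FALSE, TRUE))
  # an age band without the sign requirement admits the severity-0 patient
  age_band <- inclusion_criterion("a", "age_band", 2, 18)
  expect_equal(evaluate_criterion(coh, age_band)$eligible$eligible,
               c(TRUE, TRUE))
  # ... and the sign requirement removes them
  age_signs <- inclusion_criterion("a2", "age_band", 2, 18,
                                   require_signs = TRUE)
  expect_equal(evaluate_criterion(coh, age_signs)$eligible$eligible,
               c(FALSE, TRUE))
})

test_that("widening a band never decreases inclusion", {
  set.seed(17)
  for (s in 1:5) {
    coh <- generate_cohort(cohort_config(n_patients = 20L, seed = s))
    lows <- c(1, 0.75, 0.5, 0.25, 0)
    ups <- c(1.5, 2, 2.5, 3, Inf)
    pct <- mapply(function(lo, up) {
      evaluate_criterion(coh, inclusion_criterion("w", "asis_band", lo, up)
                         )$percent_included
    }, lows, ups)
    expect_true(all(diff(pct) >= 0))
  }
})

test_that("cross-tabulation agrees with patient-wise enumeration", {
  a <- inclusion_criterion("a", "age_band", 4, 21, require_signs = TRUE)
  b <- inclusion_criterion("b", "asis_band", 0.5, 2)
  # identical criteria: nobody is in one trial only
  coh <- generate_cohort(cohort_config(n_patients = 19L, seed = 33))
  same <- cross_tabulate(coh, a, a)
  expect_equal(same$pct_a_only, 0)
  expect_equal(same$pct_b_only, 0)
  expect_equal(same$pct_both_included + same$pct_both_excluded, 100)

  # disjoint bands covering everyone: no overlap in either direction
  lowband <- inclusion_criterion("lo", "age_band", 0, 10)
  hiband <- inclusion_criterion("hi", "age_band", 10 + 1e-9, Inf)
  xt <- cross_tabulate(coh, lowband, hiband)
  expect_equal(xt$pct_both_included, 0)
  expect_equal(xt$pct_both_excluded, 0)
  expect_equal(xt$pct_a_only + xt$pct_b_only, 100)

  # random cohorts against brute-force enumeration over patients
  for (s in 1:5) {
    coh <- generate_cohort(cohort_config(n_patients = 17L, seed = 40 + s))
    fv <- first_visits(asis_scores(coh))
    ea <- fv$age_years >= a$lower & fv$age_years <= a$upper & fv$severity > 0
    eb <- fv$asis >= b$lower & fv$asis <= b$upper
    n <- nrow(fv)
    xt <- cross_tabulate(coh, a, b)
    expect_equal(xt$pct_both_included, round(100 * sum(ea & eb) / n, 1))
    expect_equal(xt$pct_both_excluded, round(100 * sum(!ea & !eb) / n, 1))
    expect_equal(xt$pct_a_only, round(100 * sum(ea & !eb) / n, 1))
    expect_equal(xt$pct_b_only, round(100 * sum(!ea & eb) / n, 1))
  }
})

test_that("reports are invariant to cohort row order", {
  coh <- generate_cohort(cohort_config(n_patients = 15L, seed = 50))
  perm <- sample(nrow(coh))
  cr <- criteria_catalog()[["asis_0.5_2"]]
  expect_equal(evaluate_criterion(coh[perm, ], cr)$percent_included,
               evaluate_criterion(coh, cr)$percent_included)
})
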