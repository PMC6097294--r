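test_that("the generator is reproducible and respects its ranges", {
  cfg <- cohort_config(seed = 5)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1, coh2)

  pt <- patient_table(coh1)
  expect_equal(nrow(pt), 38L)
  expect_true(all(pt$n_visits >= 2L & pt$n_visits <= 9L))
  expect_true(all(pt$span_years >= 0.94 - 1e-9 & pt$span_years <= 6.36 + 1e-9))
  expect_true(all(pt$first_age >= 2 & pt$first_age <= 25))
  expect_setequal(unique(coh1$centre), c("centre_1", "centre_2"))

  # a different seed gives a different cohort
  expect_false(identical(generate_cohort(cohort_config(seed = 6)), coh1))
})

test_that("generated scores respect the scale at every visit", {
  for (s in 1:5) {
    coh <- generate_cohort(cohort_config(seed = s))
    expect_equal(nrow(validate_visits(coh)), 0L)
    tot <- total_severity(coh)
    expect_true(all(tot >= 0L & tot <= 56L))
    # subdomain sums equal the severity totals by construction
    expect_equal(as.integer(rowSums(coh[, npc_domains()$domain])), tot)
    # monotone disease course by default
    sp <- split(tot, coh$patient_id)
    expect_true(all(vapply(sp, function(v) all(diff(v) >= 0), logical(1))))
  }
})

test_that("seizure flags are coupled to the seizure domain score", {
  coh <- generate_cohort(cohort_config(seed = 8))
  expect_equal(coh$seizure_observed, coh$seizures > 0L)
  # once seizures appear they persist (onset-age model)
  sp <- split(coh$seizure_observed, coh$patient_id)
  expect_true(all(vapply(sp, function(v) all(diff(as.integer(v)) >= 0),
                         logical(1))))
})

test_that("a noiseless single-class cohort has ASIS pinned to the rate", {
  cfg <- cohort_config(seed = 10, subgroup_slopes = 1.0, subgroup_weights = 1,
                       severity_noise_sd = 0, seizure_extra_slope_sd = 0,
                       seizure_fraction = 0)
  coh <- asis_scores(generate_cohort(cfg))
  # integer rounding of the ordinal scale bounds |ASIS - rate| by 0.5/age
  expect_true(all(abs(coh$asis - 1.0) <= 0.5 / coh$age_years + 1e-12))
  # ... and hence bounds the per-patient ASIS drift rate
  sl <- asis_slopes(coh)
  pt <- patient_table(coh)
  expect_true(all(abs(sl$slope) <= 2 / (pt$first_age * pt$span_years)))
})

test_that("infeasible configurations are rejected with a diagnostic", {
  expect_error(cohort_config(subgroup_slopes = rep(60, 6)), "saturates")
  expect_error(cohort_config(subgroup_weights = c(1, 1)), "length")
  expect_error(cohort_config(subgroup_weights = rep(0.1, 6)), "sum to 1")
  expect_error(cohort_config(severity_noise_sd = -1), "non-negative")
  expect_error(cohort_config(visits_range = c(1, 9)), "min >= 2")
})

test_that("subdomain allocation is exact, capped and deterministic", {
  expect_equal(unname(allocate_subdomains(56L)), unname(domain_maxima()))
  expect_true(all(allocate_subdomains(0L) == 0L))
  a20 <- allocate_subdomains(20L)
  expect_equal(sum(a20), 20L)
  expect_true(all(a20 <= domain_maxima()))
  expect_identical(a20, allocate_subdomains(20L))

  # exhaustive feasibility over every achievable total
  for (tot in 0:56) {
    a <- allocate_subdomains(tot)
    expect_equal(sum(a), tot)
    expect_true(all(a >= 0L & a <= domain_maxima()))
  }
  # minimum-score constraint honoured (post-onset seizure scoring)
  mins <- stats::setNames(integer(16), npc_domains()$domain)
  mins["seizures"] <- 1L
  a <- allocate_subdomains(3L, min_scores = mins)
  expect_gte(a[["seizures"]], 1L)
  expect_equal(sum(a), 3L)
  # a forbidden domain stays at zero
  m <- domain_maxima(); m[["seizures"]] <- 0L
  a2 <- allocate_subdomains(51L, maxima = m)
  expect_equal(a2[["seizures"]], 0L)
  expect_equal(sum(a2), 51L)
  expect_error(allocate_subdomains(57L), "0\\.\\.56")
})

test_that("treatment series follow their configuration", {
  cfg <- treatment_config(seed = 4)
  obs1 <- generate_treatment_series(cfg)
  expect_identical(obs1, generate_treatment_series(cfg))
  expect_equal(length(unique(obs1$patient_id)), 10L)
  sp <- split(obs1, obs1$patient_id)
  for (p in sp) {
    expect_equal(p$time_on_treatment[1L], 0)
    expect_gte(nrow(p), 2L)
    expect_lte(nrow(p), 4L)
    dur <- max(p$time_on_treatment) * 12
    expect_gte(dur, 2.7)
    expect_lte(dur, 21.16)
  }
  # noiseless series recover the slope exactly
  noiseless <- generate_treatment_series(treatment_config(seed = 4,
                                                          noise_sd = 0))
  fit <- suppressWarnings(fit_treatment_model(noiseless))
  expect_equal(fit$fixed_slope, -0.06, tolerance = 1e-8)
})
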