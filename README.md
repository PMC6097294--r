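# asiskit

Analysis toolkit for studying disease progression in Niemann-Pick disease
type C (NPC) with the **annual severity increment score (ASIS)**.

NPC is a rare, clinically heterogeneous neurodegenerative lysosomal storage
disease. Clinical status is tracked with a composite severity score — here
the NIH clinical severity scale minus hearing: 8 major neurological domains
scored 0–5 and 8 minor domains scored 0–2, so totals range 0–56. Because
severity accrues approximately linearly with age in most patients, the ratio

```
ASIS = total severity score / age at assessment        [severity units / year]
```

is an index of a patient's annual progression rate. If ASIS is stable over
time it can stratify patients for clinical trials by *rate of progression*
rather than by age, predict future severity, and quantify response to
therapy. `asiskit` implements that whole analysis chain:

- **Severity scale model** — domain definitions, score validation, composite
  totals with domain exclusions (`npc_domains()`, `total_severity()`).
- **ASIS metrics** — per-visit ASIS, per-patient ASIS rate of change
  (OLS on time since first visit), stability via the Tukey 1.5·IQR whisker
  rule, quartile summaries, Gaussian KDE with Silverman's bandwidth
  (`asis_scores()`, `asis_slopes()`, `classify_stability()`).
- **Latent-class mixture regression** — a hand-rolled EM fit of K regression
  lines of severity on age with mixture weights and shared residual sd,
  plus nearest-line subgroup assignment and category-shift tables
  (`fit_latent_class_lines()`, `assign_subgroup()`).
- **Subdomain panels** — exhaustive Spearman scans of all 8/28/56
  single/pair/triad major-domain subsets against the composite total, with
  and without the subset's own contribution, and questionnaire rank
  aggregation (`subset_scan()`, `panel_correlation()`, `aggregate_ranks()`).
- **Trial stratification** — eligibility under age bands (as used by real
  NPC trials) versus ASIS bands, cross-tabulations and seizure-group
  breakdowns (`criteria_catalog()`, `evaluate_criterion()`,
  `cross_tabulate()`).
- **Prognosis** — through-origin severity trajectories from a first or mean
  ASIS, scored per patient by maximum absolute deviation (MAD), with
  seizure and follow-up-window summaries (`patient_mad()`,
  `group_mad_summary()`, `windowed_mad()`).
- **Treatment effect** — random-intercept linear mixed model of on-treatment
  ASIS over time, reported as ASIS units/year and percent annual change
  (`fit_treatment_model()`).
- **Synthetic cohort generator** — seeded longitudinal cohorts with the
  statistical structure the analyses assume (six progression-rate classes,
  two centres, 2–9 visits over up to ~6.4 years, ~47% seizure group), so
  every stage is testable end to end without patient data
  (`generate_cohort()`, `generate_treatment_series()`).

## Worked example

```r
library(asiskit)

coh <- generate_cohort(cohort_config(seed = 42))
fv  <- first_visits(asis_scores(coh))
cohort_summary(fv$asis)
#>    n   median        q1       q3
#> 1 38 1.152419 0.5832333 2.034482

sl <- classify_stability(asis_slopes(coh))
mean(sl$stable)               # 0.89 -- most patients progress at a constant rate

eligibility_table(coh)[, c("criterion", "percent_included")]
#>           criterion percent_included
#> 1    miglustat_gt12             47.4
#> 2  arimoclomol_2_18             73.7
#> 3 cyclodextrin_4_21             76.3
#> 4        asis_0.5_2             50.0
#> 5       asis_0.75_2             36.8
#> 6          asis_1_2             23.7
#> 7      asis_0.5_2.5             78.9
#> 8     asis_0.75_2.5             65.8
#> 9        asis_1_2.5             52.6

group_mad_summary(coh, stratify_by_seizure = TRUE)$summary
#>    mode       group  n median    q1   q3
#> 1 first non_seizure 23   2.14 1.154 3.08
#> 2 first     seizure 15   4.33 2.486 7.92
#> 3  mean non_seizure 23   1.27 0.767 1.60
#> 4  mean     seizure 15   2.29 1.848 3.79

fit_treatment_model(generate_treatment_series(treatment_config(seed = 42)))
#> On-treatment ASIS mixed model (REML, 10 patients, 27 observations)
#>   fixed slope: -0.0573 ASIS units/year (SE 0.0151, Wald p = 0.000142)
#>   fitted baseline: 0.9862; percent annual change: -5.8%
#>   random intercept sd: 0.4252; residual sd: 0.0443
```

Reading the output: first-visit ASIS quartiles (0.58–2.03) describe the
spread of progression rates; 89% of patients fall inside the Tukey whiskers
of the ASIS-slope distribution, i.e. their rate is stable. Age-band trial
criteria admit 47–76% of the cohort but span the full severity range,
while ASIS bands (e.g. 0.5–2: 50%) remove both the very mild and very
severe extremes. Predicting severity from the *mean* of a patient's ASIS
values halves the median prediction error (MAD) relative to a single
first-visit ASIS, and seizure-group patients are systematically harder to
predict. The mixed model recovers the generator's −0.06 units/year
on-treatment ASIS decline.

A command-line front end over the same functions is installed at
`system.file("exec", "asis-kit", package = "asiskit")` with subcommands
`simulate`, `asis`, `stability`, `subgroups`, `subdomains`, `ranks`,
`stratify`, `prognose`, `treatment`.

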