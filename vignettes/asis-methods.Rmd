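---
title: "ASIS methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ASIS methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asiskit)
```

This vignette is the package's account of the science it implements: the
severity scale, the ASIS statistic and its stability model, the
latent-class mixture regression, the subdomain-panel analysis, the trial
eligibility simulation, the MAD-based prognosis model, the on-treatment
mixed model, and the synthetic cohort generator that ties the test suite
together. It also records the numerical and design choices that were
genuinely open, and what the tests do and do not demonstrate.

## The severity scale

Niemann-Pick disease type C severity is scored on the NIH composite
clinical severity scale *minus hearing* (hearing is not comparably
measured across centres and is absent from the data model entirely, not
merely excludable). Eight major neurological domains — eye movement,
ambulation, memory, speech, swallowing, fine motor skills, cognition,
seizures — are scored 0–5; eight minor domains — cataplexy, behavioural
changes, narcolepsy, psychiatric symptoms, hyperreflexia, incontinence,
auditory brain-stem response, respiratory signs — are scored 0–2. The
major-domain total therefore maxes at 40 and the overall total at 56. The
per-major maximum of 5 is the only assignment consistent with both
printed maxima (8 × 5 = 40); scores are ordinal integers and fractional
values are rejected. `total_severity()` accepts an `exclude` argument for
reduced panels (e.g. seizure-free scoring of the treatment cohort's
8-domain variant).

## ASIS and its stability

For a visit at age $a$ with severity $S$, $\mathrm{ASIS} = S/a$
(severity units per year); it is undefined at age 0, and ages must be
decimal years. If severity grows exactly as $S = r\,a$, every visit has
ASIS $= r$ and the per-patient ASIS trajectory is flat — this exact form
of the stability claim is a test invariant, as is scale consistency
(multiplying severities by $c$ multiplies ASIS and slopes by $c$).

Per-patient rates of ASIS change are ordinary least-squares slopes of
ASIS on *time since first visit*. Regressing on absolute age gives the
identical slope; time-since-first is used for numerical conditioning.
Stability is the classic Tukey box-plot rule: a slope is stable when it
lies in $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ of the
cohort slope distribution. All quartiles in the package use linear
interpolation between order statistics (`quantile` type 7) — the
convention had to be fixed somewhere, and type 7 is R's default and the
one the oracle tests enumerate directly. At least 4 slopes are required
before the whisker rule is meaningful.

Kernel density summaries use a Gaussian kernel with Silverman's
bandwidth $h = 0.9 \min(\hat\sigma, \mathrm{IQR}/1.34)\, n^{-1/5}$,
computed by the explicit formula and cross-checked in tests against
`stats::bw.nrd0`; degenerate (zero-spread) samples are rejected rather
than given an arbitrary bandwidth. Location and dispersion contrasts
(seizure vs non-seizure, first vs mean ASIS) use Wilcoxon–Mann–Whitney
and Ansari–Bradley tests with the normal approximation, reported as
statistic plus p-value only. Seizure stratification is a grouping
argument (`by=`) on the summary functions rather than separate
operations.

## Latent-class mixture regression

Progression subgroups are modelled as a $K$-component mixture of linear
regressions of severity on age,
$y \mid k \sim \mathcal N(\alpha_k + \beta_k x,\ \sigma^2)$ with weights
$\pi_k$, fit by EM. Choices that were open:

- **Intercepts** are free by default (the general case), with
  `intercept = FALSE` forcing lines through the origin to match the ASIS
  construction.
- **Homoscedastic residuals** (one $\sigma$ across classes) by default —
  the simplest model consistent with parallel progression fans;
  `common_sd = FALSE` enables per-class variances.
- **Initialisation**: class slopes are seeded at quantiles of the
  per-point severity/age ratios, a natural scale for progression lines;
  EM is initialisation-sensitive, so `n_restarts` jittered restarts are
  run (seeded, reproducible) and the best log-likelihood kept.
- **Canonical labels**: classes are relabelled by ascending slope, making
  fits invariant to label permutation and point order.
- **Convergence**: log-likelihood change below `tol` (default $10^{-8}$)
  or `max_iter`; the observed-data log-likelihood trace is retained and
  its monotonicity asserted in tests. Non-convergence returns the fit
  with `converged = FALSE` plus a warning rather than an error.
- $K = 1$ reduces exactly to ordinary least squares (verified against
  `lm`).

Patients are assigned to the class whose line is nearest in *vertical*
(severity) distance at the visit's age — the initial severity score
"closest" to a line — with ties broken toward the lower class index. The
fit uses one point per patient (first visit) by default, since each
patient should appear once in the cross-sectional fan; pooling all
visits is available via a flag in the scan functions. Under the default
generator, adjacent class lines are only ~0.6 severity units apart at
the youngest first ages (2 years), where no assignment rule can be
reliable at residual sd 1; the assignment-accuracy tests therefore use
first ages of 8–25 years, where adjacent lines are separated by at
least ~2.4 units and accuracy is 92–100% across seeds.

## Subdomain panels and rank aggregation

`subset_scan()` enumerates every 1-, 2- or 3-subset of the 8 major
domains ($\binom{8}{1} = 8$, $\binom{8}{2} = 28$, $\binom{8}{3} = 56$
rows) and computes tie-aware Spearman correlations of the subset sum
with the composite total, both *including* the subset's own scores in
the total and *excluding* them (the honest version, since a subset
trivially correlates with a total it contributes to). Minor domains are
not scanned combinatorially, but `panel_correlation()` accepts any
domain set — e.g. the five quality-of-life domains (ambulation,
swallowing, speech, cognition, fine motor skills) that clinicians and
families independently rank most important. Spearman p-values use the
t approximation with $n-2$ degrees of freedom. A subset whose sum (or
whose complement total) is constant has no defined correlation and is
reported as `NA` rather than aborting the scan.

Questionnaire responses (each respondent ranks items 1 = most impact
upward) are aggregated by summing per-item ranks and placing sums in
ascending order. The tie rule is dense ranking — tied sums share the
lower position and the next distinct sum takes the next position — a
documented choice, since published rankings rarely state one.

## Trial eligibility simulation

Eligibility is evaluated at each patient's *first* visit (each patient
appears once). Age bands mirror three real NPC trials — miglustat
(> 12 years), arimoclomol (2–18) and intrathecal
2-hydroxypropyl-β-cyclodextrin (4–21) — each coupled with a
neurological-sign requirement (severity > 0), as real trials exclude
pre-symptomatic patients. ASIS bands (0.5–2, 0.75–2, 1–2 and the
extended 0.5–2.5, 0.75–2.5, 1–2.5) need no sign requirement: a positive
lower bound excludes severity-0 patients automatically. Band endpoints
are inclusive on both sides — the natural reading of "0.5 to 2" — and
the cyclodextrin trial's registered 2–25 band plus a 12–60 miglustat
variant are available behind `criteria_catalog(extended = TRUE)`.
Percentages are rounded half-up to one decimal for report parity;
monotonicity (widening a band never loses patients) is a tested
invariant.

## Prognosis by maximum absolute deviation

A patient's predicted trajectory is a straight line through the origin
with slope equal to a reference ASIS: the first-visit value, or the
unweighted mean over all visits (including the first). The
goodness-of-fit statistic is the per-patient **maximum** absolute
deviation between observed and predicted severity over all visits —
under the first-ASIS mode the first visit deviates by 0 by construction,
so the maximum is attained later. Groups are summarised by the median
and IQR of per-patient MADs (per individual the statistic is a single
maximum; the group summary is the median of those maxima). Follow-up
windows assign each patient once, by total span (last minus first age),
to right-closed intervals (0,2], (2,4], (4,6]; the boundary rule is a
documented choice, and spans beyond 6 years fall into the last window
with a warning.

## On-treatment mixed model

The treatment analysis models per-visit ASIS against years on treatment
with a patient-level random intercept:
$\mathrm{ASIS}_{it} = \beta_0 + \beta_1 t_{it} + u_i +
\varepsilon_{it}$. REML is the default (ML behind a flag). Baseline
assessments enter at $t = 0$. The slope's p-value is a Wald test with
the normal approximation. The percent annual change is
$100\,\beta_1/\beta_0$ — the denominator is the model's own fitted
baseline, which is the only internally consistent choice when baseline
median, mean and the slope/percent pair would each imply different
values; the fit reports all components so the discrepancy is visible
rather than resolved. With one observation per patient the random
intercept is unidentifiable and the fit falls back to ordinary least
squares, flagged `singular = TRUE` with a warning.

## The synthetic cohort generator

The generator exists so that every analysis stage is exercised
end-to-end without patient-level data, which are not published for this
disease cohort. Its defaults are fixed once to emulate the structure of
the real two-centre study: 38 patients in 2 centres; 2–9 visits per
patient spanning 0.94–6.36 years; six latent progression classes with
slopes 0.2, 0.5, 0.9, 1.4, 2.1, 3.0 severity units/year and weights
(0.10, 0.22, 0.25, 0.20, 0.13, 0.10), chosen so first-visit ASIS
quartiles bracket roughly 0.5–1.5; first ages uniform on 2–25 years;
per-visit Gaussian severity noise with sd 1; a 47% seizure group whose
members additionally receive a per-visit progression-rate wobble
(sd 0.3 units/year), making their trajectories genuinely harder to
predict; and monotone non-decreasing severity by default (progressive
disease), with a flag allowing decreases such as seizure scores
responding to medication.

Integer ordinal scores are a hard invariant: per-visit totals are
rounded, clamped to 0–56, and allocated across the 16 subdomains by
largest-remainder apportionment with capped redistribution
(deterministic; ties break in domain order), so subdomain sums equal
totals at every visit. A consequence worth stating: in a noiseless
single-class cohort the per-visit ASIS equals the class rate only up to
rounding, $|\mathrm{ASIS} - r| \le 0.5/a$, and the tests assert that
rounding-tight bound rather than exact equality. Seizure flags are
coupled to the scores — the seizure domain is 0 before a random onset
age and at least 1 after it (given a positive total), and
`seizure_observed` is derived from the score — so flag and score can
never disagree.

The treatment-series generator draws 10 patients with baseline ASIS
uniform on 0.38–1.94, durations of 2.7–21.16 months, 2–4 assessments
(the first at treatment start) and ASIS declining at −0.06 units/year
plus observation noise (sd 0.03).

What the generator does *not* emulate: genotype–phenotype structure,
centre-specific scoring drift, informative visit timing, mortality or
drop-out, and any correlation structure among subdomains beyond the
shared total. Passing tests on synthetic cohorts therefore demonstrate
the *statistical machinery* — parameter recovery, invariants, oracle
agreement, directional findings (mean-ASIS predictions beat first-ASIS;
seizure-group MADs exceed non-seizure; ASIS bands trim the severity
extremes that age bands admit) — not clinical conclusions about real
patients.

## Problem sizes and test design

The suites use cohorts of 38 patients (the study's size) and, where
replication is needed, 100 seeded replicates for directional claims,
50 for the treatment-slope average, and 150 points for 6-class mixture
recovery — sizes at which the checked effects are stable across seeds
while the full suite runs in about a minute. Oracles are independent
reimplementations: Spearman against a hand-written rank-then-Pearson
computation, whiskers against direct quartile enumeration,
cross-tabulation against patient-wise counting, EM's $K=1$ case against
`lm`, and the Silverman formula against `bw.nrd0`.

## Known limitations

- The EM fit can converge to local optima for overlapping classes;
  restarts mitigate but do not eliminate this, and `converged`/`loglik`
  should be inspected when $K$ is large relative to the data.
- The whisker stability rule is descriptive, not inferential; with
  heavy-tailed slope distributions the 1.5·IQR fences are conventional
  rather than calibrated.
- Percent annual change inherits any bias in the fitted baseline; for
  cohorts with strongly skewed baselines the median baseline may be a
  fairer denominator, and both are reported.
- MAD is a worst-case statistic and grows mechanically with follow-up
  span and visit count; comparisons across groups with very different
  schedules should use the windowed summaries.
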