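---
title: "Methods: cost-of-illness and quality-of-life analysis for Crohn's disease surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-of-illness and quality-of-life analysis for Crohn's disease surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdburden)
```

# Scope and design

`cdburden` implements a complete analysis pipeline for self-report
cost-of-illness surveys of adult Crohn's disease (CD) patients.  One row of
the canonical cohort table is one respondent's questionnaire: demographics,
the patient-completed Harvey-Bradshaw index (P-HBI), EQ-5D-3L levels,
work-status and working-time answers, hours of assistance by caregiver type,
medical resource use, out-of-pocket expense ranges and financial transfers.
The analysis takes the societal perspective and the human capital approach
for paid work, the prevalence method for permanent work disability, and the
opportunity-cost method for unpaid work and informal care.

Two principles shape everything downstream:

* **Per-outcome exclusion, no imputation.**  Self-reported answers that are
  internally inconsistent (a diagnosis age above the current age, more days
  missed than working days in the month, more private than total
  consultations, a disability level without a pension) are set missing
  *field by field* and logged; the respondent is never dropped.  Every
  outcome is then analysed over its complete cases, which is why each
  reported statistic carries its own `n`.
* **Everything is configurable but nothing is silent.**  Value sets, norms,
  unit costs, the abdominal-mass weight, the friction period and the
  covariate set are explicit arguments or config entries; validation
  replacements and clamped formula inputs are logged because the credibility
  of a self-report costing study rests on its data-cleaning rules.

# Disease-activity scoring

The P-HBI sums: general well-being (0–4), abdominal pain (0–3), one point
per liquid stool per day, the abdominal-mass item, and one point per
complication present in the previous week (arthralgia, uveitis, erythema
nodosum, aphthous ulcers, pyoderma gangrenosum, anal fissure, fistula,
abscess).  Complications reported only *earlier* than the previous week
identify a penetrating (fistulising) course when the complication is a
fistula, but never enter the score.  A score above 4 defines active disease;
the boundary case 4 is remission.

**Abdominal mass (design choice).**  A clinician scores the mass item 0–3 by
palpation; a self-report questionnaire can only ask *present / absent / do
not know*.  We score `present` as 1 point by default with the weight
exposed as `mass_points`, and score `unknown` as 0 even when the item is
included — the defensible reading of an instrument that allows "do not
know".  The with/without-mass analyses (`include_mass`) let users check that
classification is insensitive to this choice; by construction the two
classifications can only disagree on respondents whose mass-free score is
exactly 4 with a mass present.

# Utility scoring

An EQ-5D-3L value set is stored as a small CSV (`dimension, level,
decrement`) with two pseudo-dimensions: `constant` (any-problem intercept)
and `n3` (any-level-3 term).  Utility is
`1 − constant·[any level>1] − n3·[any level 3] − Σ per-dimension decrements`,
so state `11111` is anchored at 1 for every tariff.  The engine is
tariff-agnostic; tests verify it against a brute-force enumeration of all
243 states.

The package ships the UK MVH A1 time trade-off tariff (publicly known
coefficients) as the working default, and a **synthetic stand-in** for the
Polish tariff (`poland_synthetic`): the genuine Polish TTO coefficients are
not redistributable here, so the stand-in only mimics the N3 structure with
plausible magnitudes.  Any substantive Polish analysis must load the real
tariff file.  The same caveat applies to the packaged population-norms
table; lookups use half-open age bands `[low, high)`, so a respondent aged
exactly 35 falls into the 35–44 band.

# The cost engine

## Unit cost of paid work

The human capital unit cost is GDP per worker-hour scaled by the
Cobb-Douglas output elasticity of labour:
`gdp / (workers × max_hours) × elasticity`.  With the packaged Polish 2015
macro block (GDP €420,164.45 million, 16,234 thousand employed persons,
2016 maximum annual hours, elasticity 0.65) this yields €8.34/h after
rounding to cents.  The sensitivity switch `unit_cost_basis` substitutes
GDP per capita per hour, a user-supplied average wage, or a user-supplied
gross value added per hour; the last two have no packaged defaults because
no authoritative per-hour values are bundled.  All paid-work components are
homogeneous of degree 1 in the unit cost, which is what makes this a pure
rescaling sensitivity.

## Absenteeism, presenteeism, overall reduction

With `A_d` full days missed in the previous month, `A_h` single hours missed
in the last five working days, and maximum working time `L_d` days/month ×
`L_h` hours/day:

* `R_A = (A_d·L_h + (A_h/5)·(L_d − A_d)) / (L_d·L_h)` — the five-day recall
  of single hours is extrapolated as an average over the `L_d − A_d` days
  actually worked.
* `R_P = 0.1 ×` presenteeism score (0 = no impact … 10 = completely
  prevented), treated as representative of the month.
* `R_O = R_A + (1 − R_A)·R_P` — presenteeism applies only to time at work,
  so `R_O ≥ max(R_A, R_P)` and hours decompose exactly:
  `hours_A + hours_P = L_d·L_h·R_O`.

Numerical choices: `R_A` is clamped to `[0, 1]` with a warning (validation
should already have removed `A_d > L_d`; a clamp signals an extreme but
plausible answer, e.g. very large `A_h`).  Respondents without occupational
activity contribute **zeros**, not missing values — they belong in the
denominator of whole-sample cost means.  Working respondents with
"unspecified" working time fall back to the configurable full-time norm of
21 days × 8 hours (168 monthly hours); part-time workers use their own
reported `L_d`, `L_h` throughout.

## Early departure from the labour market and the friction period

Only registered departures count: respondents on a social or disability
pension.  The monthly cost is `disability level × 168 h × unit cost`, with
100% inability assumed for social-pension recipients (that pension is
granted only for full inability arising before adulthood or during
education).  A pension with neither a disability level nor the
social-pension flag yields a missing cost.

The optional friction period (conventionally 90 days) zeroes the cost of
departures that occurred *longer ago* than the period — under the friction
view a replacement worker has long since restored output — and keeps
departures within the window at full value.  An unknown departure time keeps
the cost, with a warning: the conservative direction, since dropping it
would silently understate the burden.  Short-term components are untouched
by construction, so a friction run differs from a human-capital run in the
early-departure column only (bit-identical elsewhere; this is tested).

## Unpaid work and informal care

Two measurement concepts are kept strictly apart:

* **Replaced unpaid work** — all hours of assistance the respondent actually
  received (family, non-relative unpaid, professional/paid), i.e. only the
  part of lost unpaid work somebody actually had to perform.
* **Informal care** — the unpaid subset (family + non-relatives).

Both are valued at the opportunity-cost wage (€5.27/h, the average wage per
maximum working hour) and scaled by 4.345 weeks/month.  The *total* indirect
cost adds informal care plus only the **uncompensated** part of replaced
unpaid work (professional/paid hours), so an hour of family help is never
counted twice.  The decomposition identity
`informal + uncompensated = replaced unpaid work` is a tested invariant.

## Direct, out-of-pocket and transfer costs

Publicly funded consultations are `(total − private) × €7.57`; private
consultations use the respondent's own reported average price.
Hospitalisations are priced by type: one-day stays €109.80, one surgical
stay €1553.16 when reported, remaining stays as medical €975.98.  Drug costs
are defined-daily-dose based — `units/day × 30.44 days/month × unit cost`
for oral drugs — while biologics use the recommended 12-month dosing divided
by 12 (adalimumab 160/80 mg induction then 40 mg every other week
= 1240 mg/year; infliximab 5 mg/kg at weeks 0, 2, 6 then every 8 weeks
= 8 infusions/year at the 64.71 kg reference weight, without vial rounding),
plus a €54.90 monthly diagnostics package for biologic users.  The dosing
constants live in the unit-cost YAML, not in code.

Out-of-pocket answers come as predefined ranges (€0–23.5–46.9–93.8–140.8)
or an open amount above the top range; a range is valued at its midpoint
with the bounds as extreme valuations, an open amount at itself.  Cost
outcomes can be normalised as a share of monthly GDP per capita
(annual €10,900 / 12).  All internal currency is EUR; PLN input is converted
at 4.2624 PLN/€ on read.  Monetary values are kept at full floating
precision and rounded only in reports.

# Statistical inference

* **Descriptives** use mean/SD and quantiles with linear interpolation
  between order statistics (R type 7) — the package-wide quantile
  convention, chosen because it is R's default and therefore the least
  surprising to reviewers re-running pieces by hand.
* **Spearman's ρ** is computed as the Pearson correlation of mid-ranks
  (average ranks for ties) with the two-sided t approximation for p.
  Subgroup comparisons use the Wilcoxon rank-sum test (exact for small
  tie-free samples, normal approximation with continuity correction
  otherwise), the signed-rank test for the paired patient-vs-norm utility
  comparison (zero differences dropped), and Pearson's χ² without continuity
  correction for categorical tables.
* **Agreement** between the P-HBI classification and the clinician's last
  assessment is the observed agreement plus Cohen's κ with expected
  agreement from marginal products; the p-value uses the large-sample
  standard error under independence.  If both raters use a single category,
  agreement is 100% and κ is reported undefined.
* **Fractional logit** (quasi-binomial, logit link) models utilities in
  `[0, 1]`.  **Two-part models** handle the zero mass and right skew of
  costs: a logistic model for `P(cost > 0)` and a log-link GLM on positive
  costs, gamma family by default.  The default follows the modified Park
  test logic (regress squared residuals on log fitted values; a slope near 2
  indicates gamma variance), which is also exposed as
  `model_selection_diagnostics()` and reported, never auto-applied.
* **Contrasts as average adjusted predictions.**  Every observation is
  predicted under each group assignment and averaged; the difference gets a
  delta-method CI with analytically derived gradients (cross-checked against
  finite differences in the tests) and robust **HC1** parameter covariances.
  HC1 was chosen because the quasi-likelihoods here are working models (the
  fractional-logit variance is misspecified by construction) and because it
  matches the small-sample scaling of the robust estimator in the major
  commercial implementation of two-part models, easing cross-checks.  The
  two parts are treated as independent blocks — the standard two-part
  assumption.  Degenerate inputs are explicit: all-zero costs give adjusted
  means of 0; a group without positive costs gets a zero part-2 prediction
  and a flag; all-positive costs degenerate part 1 to 1.
* **Sample size** uses the unequal-variance normal approximation
  `n = (z₁₋α/₂ + z_power)² σ²(1 + ratio/allocation) / Δ²`, inflated by
  `1/(1 − missing rate)` and rounded up.  The reference-group SD is a
  required input, not a default, because no authoritative value ships with
  the package.
* **No multiplicity correction** is applied, mirroring the single-study
  design the pipeline reproduces; a Bonferroni threshold can be applied by
  the user on the emitted p-values.

# The synthetic cohort generator

The generator exists so that every downstream stage — validation, scoring,
costing, modelling, reporting — is testable without patient-level study
data.  Its defaults encode published two-stratum marginals as a fixed
"stated world":

| Parameter | Default | Emulates |
|---|---|---|
| remission fraction | 0.47 | stratum sizes 93/105 of ~200 respondents |
| P-HBI, remission | Binomial(4, 0.47) | mean 1.88 on 0–4 |
| P-HBI, active | 5 + NegBin(μ 4.2, size 1.5) | mean 9.20, SD ≈ 4 |
| employment | 0.645 / 0.552 | per-stratum occupational activity |
| pension | 0.043 / 0.152 | social/disability pension rates |
| care zero-inflation | logit(−2.6 + 0.25·P-HBI) | ≈ ¼ of patients assisted |
| family / non-relative hours | Gamma, means 8.15 / 2.80 h/wk | caregiver time summaries |
| consultations | 1 + Poisson(0.87) given any (p ≈ 0.7) | mean 1.87/month |
| private consultation price | Normal(36.61, 15.94), truncated | reported average |
| expense ranges | per-category categorical | range frequencies |
| EQ-5D link | ordered logistic, per-dimension slopes/cuts | response frequencies by stratum |

Distributional *forms* (zero-inflated gamma costs, shifted negative binomial
counts, ordered-logistic EQ-5D link, binomial presenteeism/impairment
scores) are generator choices — the sources report only summaries.  A master
seed drives a fixed per-component seed schedule (`seed × 37 + component`),
so the disease-activity block can be regenerated without re-drawing the
resource-use block.

**What the generator does and does not establish.**  By construction the
cohorts have severity-monotone presenteeism, impairment and care time,
severity-decreasing utility, zero-inflated right-skewed costs, and clean
validation (no rule fires).  They do *not* reproduce the study respondents'
joint distribution beyond these marginals and links: tail behaviour of the
P-HBI above ~20, within-stratum covariances of resource use, and the
employment–pension overlap are all invented.  A green test on synthetic data
therefore establishes that the *pipeline arithmetic and inference machinery*
behave as specified — not that the package reproduces any published estimate
beyond the deterministic constants (unit cost, GDP share) it recomputes
directly.

The paired two-group cost generator (`generate_two_group_costs`) is the
calibration harness for the two-part models: group means differ by exactly
the design effect, zeros occur with per-group probability, positives are
gamma (or log-normal).  At study-sized groups (93/105) the acceptance tests
require |bias| below 10% of a €200 effect, 95% CI coverage within binomial
error over 500 replicates, and a null rejection rate within the 99% binomial
band around 5%.

# The deposited study dataset

The patient-level data of the motivating study were deposited as a
supplementary spreadsheet whose column layout is undocumented, and the file
is not redistributable with this package.  `read_s1_dataset()` therefore
takes a user-written column mapping (canonical name → sheet column) and
returns a structured *unavailable* marker when the file is absent;
`study_targets()` then reports each published headline statistic as
unreachable with the missing input named, instead of failing.  The adapter
code path itself is exercised in tests on a synthetic stand-in export.
Consequently, comparisons against the published cohort statistics (mean
utility 0.839, €462.47 total indirect cost, ρ = −0.586, κ = 0.497, …) are
conditional on supplying that dataset and a mapping; nothing in the test
suite asserts them.

# Known limitations

* The packaged Polish tariff and norms are labelled synthetic stand-ins;
  utilities computed from them are structurally correct but not Polish
  population values.
* Biologic drug costs depend on dosing-schedule assumptions (documented in
  the unit-cost YAML); exact reproduction of any published monthly biologic
  cost is not possible from printed unit prices alone.
* The two-part delta-method CI is asymptotic; with ~60 positive
  observations per group its finite-sample coverage sits slightly below the
  nominal 95% (measured, and within the acceptance band).
* Presenteeism over the last five working days is extrapolated to the
  month; no proxy-good valuation of care time, no employer-perspective
  costing, no loss-of-leisure valuation, no EQ-5D-5L crosswalks, no
  longitudinal structure.
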