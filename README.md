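# cdburden

Cost-of-illness and quality-of-life analysis for questionnaire-based
burden-of-illness studies of Crohn's disease (CD).

## Who this is for

Health economists and biostatisticians analysing self-report surveys of CD
patients: disease activity from the patient-completed Harvey-Bradshaw index
(P-HBI), EQ-5D-3L utility indexes, and the full indirect/direct cost side of
a societal cost-of-illness study — absenteeism, presenteeism, permanent work
disability, replaced unpaid work, informal care, medical resource use,
out-of-pocket spending and transfers — with severity-stratified comparisons
that respect the zero-inflated, right-skewed nature of cost data.

## The model in brief

**Disease activity.** The P-HBI sums general well-being (0–4), abdominal
pain (0–3), one point per liquid stool per day, an abdominal-mass item and
one point per complication in the previous week; a score > 4 defines active
disease.

**Utility.** EQ-5D-3L states are valued against a configurable value set
(tariff): `U = 1 − c·[any level>1] − n3·[any level 3] − Σ decrements`, and
compared against age/sex-matched population norms.

**Paid-work productivity (human capital approach).** With `A_d` full days
missed per month, `A_h` single hours missed in the last five working days,
and maximum working time `L_d` days × `L_h` hours,

```
R_A = (A_d·L_h + (A_h/5)·(L_d − A_d)) / (L_d·L_h)      absenteeism
R_P = 0.1 × presenteeism score (0–10)                   presenteeism
R_O = R_A + (1 − R_A)·R_P                               overall
```

Hours lost per month are `L_d·L_h·R_A` and `L_d·L_h·(1−R_A)·R_P`, valued at
the unit cost of productivity loss — GDP per worker-hour scaled by the
Cobb-Douglas output elasticity of labour (0.65):
`420,164.45 M€ / (16,234 k workers × 2016 h) × 0.65 = €8.34/h`.

**Early departure from the labour market.** Prevalence method: registered
disability level × 168 monthly hours × unit cost (100% assumed for social
pensions); an optional 90-day friction period zeroes departures older than
the period and touches nothing else.

**Unpaid work and informal care (opportunity cost).** Replaced unpaid work
is all assistance the patient actually received; informal care is the unpaid
(family + non-relative) part; hours × €5.27/h × 4.345 weeks/month.  The
total indirect cost adds absenteeism, presenteeism, early departure,
*uncompensated* unpaid-work loss and informal care, so care time is never
double counted.

**Inference.** Subgroup contrasts are average adjusted predictions with
delta-method CIs: fractional logit for utilities; two-part models (logit for
any cost, gamma/log GLM for positive cost, robust HC1 variances) for costs,
with the modified Park test to check the variance family.

## Worked example

```r
library(cdburden)

ch <- generate_cohort(cohort_config(n = 200, seed = 42))  # synthetic cohort
sc <- score_cohort(ch)                                    # P-HBI, EQ-5D
table(sc$activity)
#> remission    active
#>        81       119

uc <- unit_cost_table()
round(uc$paid_work_hour_eur, 2)
#> [1] 8.34

cb <- cost_cohort(sc, uc)                                 # EUR/month
round(colMeans(cb[, c("absenteeism", "presenteeism", "early_departure",
                      "unpaid_uncompensated", "informal_care",
                      "total_indirect")], na.rm = TRUE), 2)
#>          absenteeism         presenteeism      early_departure
#>                73.21                69.10               164.73
#> unpaid_uncompensated        informal_care       total_indirect
#>                 1.91                62.70               371.64

round(gdp_share(mean(cb$total_indirect, na.rm = TRUE)), 1)  # % of GDP/capita
#> [1] 40.9

spearman_rho(sc$utility, sc$phbi_score)
#>          rho   n            p
#> 1 -0.5394632 200 1.693136e-16

mod <- data.frame(cost = cb$total_indirect, group = sc$activity,
                  age = sc$age, age_dx = sc$age_at_diagnosis,
                  comorb = as.numeric(sc$comorbidities),
                  surgery = as.numeric(sc$surgery_count > 0))
two_part_cost_model(mod, "cost", "group",
                    c("age", "age_dx", "comorb", "surgery"))
#> Adjusted means (average adjusted predictions):
#> remission    active
#>  127.4385  544.9468
#> difference -417.5082 (95% CI -543.3103 to -291.7061), p = 7.786e-11, n = 200
#> adjusted for: age, age_dx, comorb, surgery
```

Read the numbers as: in this synthetic cohort the mean total indirect cost
is €371.64 per patient-month (40.9% of monthly GDP per capita), utilities
fall with disease activity (Spearman ρ = −0.54), and after adjustment the
remission subgroup costs €417.51/month less than the active subgroup.

The whole pipeline (validation → scoring → costing → tables → manifest) is
one call:

```r
run_pipeline(run_config(out_dir = "results", seed = 42,
                        generator = list(n = 200)))
```

or from a shell:

```sh
Rscript inst/cli/cdburden.R all --synthetic --n 200 --seed 42 --out-dir results
```

## Data files

`inst/extdata/` ships the unit-cost/macro configuration
(`unit_costs_poland.yaml`), the UK MVH A1 EQ-5D-3L tariff
(`eq5d3l_value_set_uk_mvh.csv`) and **synthetic stand-ins** for the Polish
tariff and population norms (`*_poland_synthetic.csv`) — replace these two
with the real published files for substantive Polish analyses (schema:
`dimension,level,decrement` and `age_low,age_high,sex,utility`).

See `vignettes/cd-burden-methods.Rmd` for assumptions, parameter
provenance, what the synthetic generator does and does not emulate, and
known limitations.
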