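Package: cdburden
Title: Cost-of-Illness and Quality-of-Life Analysis for Crohn's Disease Self-Report Surveys
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for questionnaire-based burden-of-illness
    studies of Crohn's disease: patient-completed Harvey-Bradshaw index
    (P-HBI) disease-activity scoring, EQ-5D-3L utility scoring against
    configurable value sets and population norms, a multi-component
    indirect-cost engine (absenteeism, presenteeism, early departure from
    the labour market, replaced unpaid work and informal care) valued by
    the human capital and opportunity-cost approaches, direct and
    out-of-pocket cost valuation, and severity-stratified statistical
    comparison via fractional-logit and two-part cost models with robust
    variances and delta-method confidence intervals.  A synthetic-cohort
    generator calibrated to published marginals makes the whole pipeline
    testable without access to patient-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    readxl,
    optparse,
    withr
Config/testthat/edition: 3
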