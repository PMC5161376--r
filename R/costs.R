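## Per-patient cost engine: paid-work productivity losses, early departure
## from the labour market, unpaid work and informal care, direct and transfer
## costs.  All functions are vectorised and propagate missing inputs.

#' Fractional productivity reduction due to absenteeism
#'
#' `R_A = (A_d * L_h + (A_h / 5) * (L_d - A_d)) / (L_d * L_h)`: full days
#' missed in the previous month plus single hours missed in the last five
#' working days, extrapolated to the remaining working days of the month and
#' expressed as a fraction of the monthly working time.  Values outside
#' `[0, 1]` are clamped with a warning (a clamp indicates an answer that
#' survived validation but is still extreme).
#'
#' @param A_d full working days missed in the last month.
#' @param A_h single hours missed in the last five working days.
#' @param L_d maximum working days per month.
#' @param L_h maximum working hours per day.
#' @return fraction in `[0, 1]` (`NA` on missing input).
#' @export
#' @examples
#' absenteeism_fraction(2, 3, 21, 8)  # 27.4 / 168
absenteeism_fraction <- function(A_d, A_h, L_d, L_h) {
  if (any(L_d <= 0 | L_h <= 0, na.rm = TRUE))
    stop("working time L_d, L_h must be positive")
  r <- (A_d * L_h + (A_h / 5) * (L_d - A_d)) / (L_d * L_h)
  out_of_range <- !is.na(r) & (r < 0 | r > 1)
  if (any(out_of_range))
    warning(sum(out_of_range), " absenteeism fraction(s) clamped to [0, 1]")
  pmin(pmax(r, 0), 1)
}

#' Fractional productivity reduction due to presenteeism
#'
#' One tenth of the 0-10 presenteeism score (0 = no impact, 10 = completely
#' prevented).  Out-of-range scores give `NA` with a warning.
#' @param score integer 0-10.
#' @export
presenteeism_fraction <- function(score) {
  bad <- !is.na(score) & (score < 0 | score > 10)
  if (any(bad)) {
    warning(sum(bad), " presenteeism score(s) outside 0-10 set missing")
    score[bad] <- NA
  }
  0.1 * score
}

#' Overall reduction of productivity at paid work
#'
#' Combines absenteeism and presenteeism: `R_O = R_A + (1 - R_A) * R_P`
#' (presenteeism applies only to time actually at work).
#' @param R_A,R_P fractions in `[0, 1]`.
#' @export
overall_reduction <- function(R_A, R_P) {
  if (any(R_A < 0 | R_A > 1 | R_P < 0 | R_P > 1, na.rm = TRUE))
    stop("R_A and R_P must be in [0, 1]")
  R_A + (1 - R_A) * R_P
}

#' Monthly paid-work productivity costs
#'
#' Hours missed per month are the monthly working time `L_d * L_h` times
#' `R_A` (absenteeism) and `(1 - R_A) * R_P` (presenteeism); each block of
#' hours is valued at the unit cost of productivity loss.  Respondents
#' without occupational activity contribute zeros (they are in the
#' denominators of whole-sample cost tables), with a "not applicable" note.
#' Working respondents with unspecified working time fall back to the
#' configurable full-time norm.
#'
#' @param works logical, any occupational activity.
#' @param L_d,L_h working days/month and hours/day (fallbacks applied when
#'   `works` is `TRUE` and the value is missing).
#' @param A_d,A_h,score see [absenteeism_fraction()], [presenteeism_fraction()].
#' @param unit_cost EUR per hour of lost paid work.
#' @param default_days,default_hours full-time fallback (21 d, 8 h: the
#'   full-time norm consistent with 168 monthly hours).
#' @return `data.frame` with `hours_absent`, `hours_present`,
#'   `absenteeism`, `presenteeism` (EUR/month).
#' @export
paid_work_costs <- function(works, L_d, L_h, A_d, A_h, score, unit_cost,
                            default_days = 21, default_hours = 8) {
  n <- length(works)
  works <- works %in% TRUE
  L_d <- ifelse(works & is.na(L_d), default_days, L_d)
  L_h <- ifelse(works & is.na(L_h), default_hours, L_h)
  ra <- rp <- rep(NA_real_, n)
  ok <- works & !is.na(L_d) & !is.na(L_h)
  ra[ok] <- absenteeism_fraction(A_d[ok], A_h[ok], L_d[ok], L_h[ok])
  rp[ok] <- presenteeism_fraction(score[ok])
  hours_absent <- ifelse(works, L_d * L_h * ra, 0)
  hours_present <- ifelse(works, L_d * L_h * (1 - ra) * rp, 0)
  data.frame(hours_absent = hours_absent,
             hours_present = hours_present,
             absenteeism = hours_absent * unit_cost,
             presenteeism = hours_present * unit_cost)
}

#' Monthly cost of early departure from the labour market
#'
#' Prevalence-method valuation of permanent work disability: the registered
#' level of inability to work times the average monthly working hours times
#' the unit cost of productivity loss.  Only registered departures count
#' (respondents on a social or disability pension); social-pension recipients
#' are assumed fully (100%) unable to work.  A pension without either a
#' disability level or the social-pension flag gives a missing cost.
#'
#' @param on_pension logical.
#' @param disability_level fraction 0-1.
#' @param social_pension logical; forces level 1.
#' @param unit_cost EUR/hour.
#' @param monthly_hours average working hours in a month (168).
#' @return EUR/month (0 for respondents not on a pension).
#' @export
#' @examples
#' early_departure_cost(TRUE, 0.75, FALSE, 8.34)  # 0.75 * 168 * 8.34
early_departure_cost <- function(on_pension, disability_level,
                                 social_pension = FALSE, unit_cost,
                                 monthly_hours = 168) {
  n <- max(length(on_pension), length(disability_level))
  on_pension <- rep_len(on_pension, n) %in% TRUE
  social_pension <- rep_len(social_pension, n) %in% TRUE
  disability_level <- rep_len(disability_level, n)
  level <- ifelse(social_pension, 1, disability_level)
  out <- ifelse(!on_pension, 0, level * monthly_hours * unit_cost)
  out
}

#' Apply a friction period to a prevalence-method cost
#'
#' Under the friction-cost view, productivity lost through early departure
#' only counts until a replacement worker restores output.  Departures that
#' occurred longer ago than the friction period are zeroed; departures within
#' the period keep their full monthly cost.  A missing departure time keeps
#' the cost (conservative) with a warning.  `friction_days = NULL` or `Inf`
#' disables the adjustment (identity).
#'
#' @param cost EUR/month (>= 0).
#' @param months_since_departure months since leaving the labour market.
#' @param friction_days conventional friction period, days (e.g. 90).
#' @param days_per_month calendar conversion (30.44).
#' @export
apply_friction_period <- function(cost, months_since_departure,
                                  friction_days = 90,
                                  days_per_month = 30.44) {
  if (any(cost < 0, na.rm = TRUE)) stop("costs must be non-negative")
  if (is.null(friction_days) || !is.finite(friction_days)) return(cost)
  unknown <- is.na(months_since_departure) & !is.na(cost) & cost > 0
  if (any(unknown))
    warning(sum(unknown),
            " departure time(s) unknown; cost retained under friction")
  beyond <- !is.na(months_since_departure) &
    months_since_departure * days_per_month > friction_days
  ifelse(beyond, 0, cost)
}

#' Monthly costs of replaced unpaid work and informal care
#'
#' The patient's productivity loss at unpaid work is measured as *replaced*
#' unpaid work: all hours of assistance actually received (family,
#' non-relatives, professional/paid helpers).  Informal care is the subset
#' delivered without payment (family + non-relatives).  The residual
#' (professional/paid hours) is the unpaid-work loss *not* compensated by
#' informal caregivers; it is the part that enters the total indirect cost
#' next to informal care, so care time is never double counted.  All hours
#' are valued at the opportunity-cost wage and scaled from weekly recall to
#' a month.
#'
#' @param family_hpw,nonrelative_hpw,professional_hpw hours/week by caregiver
#'   type.
#' @param wage opportunity-cost wage, EUR/hour (5.27).
#' @param weeks_per_month weekly-to-monthly conversion (4.345).
#' @return `data.frame` with `unpaid_work_loss`, `informal_care`,
#'   `unpaid_uncompensated` (EUR/month).
#' @export
#' @examples
#' care_costs(10, 0, 0)  # 10 * 5.27 * 4.345 on the first two components
care_costs <- function(family_hpw, nonrelative_hpw, professional_hpw,
                       wage = 5.27, weeks_per_month = 4.345) {
  if (any(c(family_hpw, nonrelative_hpw, professional_hpw) < 0, na.rm = TRUE))
    stop("assistance hours must be non-negative")
  total <- family_hpw + nonrelative_hpw + professional_hpw
  informal <- family_hpw + nonrelative_hpw
  data.frame(unpaid_work_loss = total * wage * weeks_per_month,
             informal_care = informal * wage * weeks_per_month,
             unpaid_uncompensated = professional_hpw * wage * weeks_per_month)
}

#' Valuation of an out-of-pocket expense answer
#'
#' A predefined range is valued at its midpoint with the two bounds as the
#' extreme valuations; an open amount above the top range (stored with
#' `low == high`) is its own value.  The relative measurement uncertainty of
#' a mean estimate is `(min - mean) / mean` and `(max - mean) / mean`.
#'
#' @param low,high EUR bounds of the answer.
#' @return `data.frame` with `mean`, `min`, `max` (EUR/month).
#' @export
#' @examples
#' out_of_pocket_valuation(23.5, 46.9)  # mean 35.2
out_of_pocket_valuation <- function(low, high) {
  if (any(low > high, na.rm = TRUE))
    stop("expense range low bound exceeds high bound")
  data.frame(mean = (low + high) / 2, min = low, max = high)
}

#' Monthly direct medical costs from the public payer's perspective
#'
#' * Publicly funded consultations: `(total - private)` times the specialist
#'   consultation unit cost; private consultations at the respondent-reported
#'   average price.
#' * Hospitalisations priced by type: one-day stays, one surgical stay when
#'   reported, the remainder as medical stays.
#' * Current pharmacotherapy from the treatment flags: defined-daily-dose
#'   consumption for oral drugs, recommended 12-month dosing divided by 12
#'   for biologics (weight-based for infliximab), plus the monthly
#'   diagnostics package for biologic users.
#'
#' @param cohort canonical cohort `data.frame`.
#' @param unit_costs a `cd_unit_costs` table.
#' @param body_weight kg used for weight-based dosing.
#' @return `data.frame` with `consult_public`, `consult_private`,
#'   `hospitalisation`, `treatment` (EUR/month).
#' @export
direct_costs <- function(cohort, unit_costs = unit_cost_table(),
                         body_weight = unit_costs$biologics$body_weight_kg) {
  uc <- unit_costs
  n_pub <- pmax(cohort$consultations_total - cohort$consultations_private, 0)
  consult_public <- n_pub * uc$direct$consultation_specialist
  priv_cost <- ifelse(cohort$consultations_private %in% 0, 0,
                      cohort$consultations_private * cohort$private_consult_cost)
  n_hosp <- cohort$hosp_count
  n_oneday <- pmin(ifelse(is.na(cohort$hosp_oneday_count) & !is.na(n_hosp),
                          0L, cohort$hosp_oneday_count), n_hosp)
  n_surg <- ifelse(cohort$hosp_surgical %in% TRUE,
                   pmin(1L, n_hosp - n_oneday), 0L)
  n_med <- pmax(n_hosp - n_oneday - n_surg, 0)
  hosp <- n_oneday * uc$direct$hospitalisation_one_day +
    n_surg * uc$direct$hospitalisation_surgical +
    n_med * uc$direct$hospitalisation_medical
  flags <- c(aminosalicylate = "tx_aminosalicylate",
             immunosuppressant = "tx_immunosuppressant",
             glucocorticoid = "tx_glucocorticoid",
             adalimumab = "tx_adalimumab",
             infliximab = "tx_infliximab")
  per_flag <- vapply(names(flags), monthly_drug_cost, numeric(1),
                     unit_costs = uc, body_weight = body_weight)
  fl <- vapply(flags, function(cn) cohort[[cn]] %in% TRUE,
               logical(nrow(cohort)))
  if (nrow(cohort) == 1L) fl <- matrix(fl, nrow = 1,
                                       dimnames = list(NULL, names(flags)))
  treatment <- as.numeric(fl %*% per_flag) +
    ifelse(fl[, "adalimumab"] | fl[, "infliximab"],
           uc$direct$diagnostics_biologic_month, 0)
  data.frame(consult_public = consult_public,
             consult_private = priv_cost,
             hospitalisation = hosp,
             treatment = treatment)
}

#' Total monthly indirect cost per respondent
#'
#' Absenteeism + presenteeism + productivity loss at unpaid work that was
#' *not* compensated by informal caregivers + informal care, plus (by
#' default) the cost of registered early departure from the labour market.
#' A missing component makes the respondent's total missing (per-outcome
#' exclusion).
#'
#' @param cb a cost-breakdown `data.frame` from [cost_cohort()].
#' @param include_early_departure include the permanent-disability component.
#' @return EUR/month vector.
#' @export
total_indirect <- function(cb, include_early_departure = TRUE) {
  out <- cb$absenteeism + cb$presenteeism + cb$unpaid_uncompensated +
    cb$informal_care
  if (include_early_departure) out <- out + cb$early_departure
  out
}

#' Per-patient monthly cost breakdown
#'
#' Runs the whole cost engine over a validated cohort and returns one row per
#' respondent with every indirect, direct, out-of-pocket and transfer
#' component plus the hours missed from paid work.  The optional friction
#' period affects only the early-departure component (short-term losses are
#' untouched by construction).
#'
#' @param cohort canonical cohort `data.frame`.
#' @param unit_costs a `cd_unit_costs` table.
#' @param friction_days friction period in days, or `NULL` (human capital
#'   approach, no friction adjustment).
#' @param include_early_departure include early departure in `total_indirect`.
#' @return `data.frame` keyed by `id` with components in EUR/month.
#' @export
cost_cohort <- function(cohort, unit_costs = unit_cost_table(),
                        friction_days = NULL,
                        include_early_departure = TRUE) {
  uc <- unit_costs
  pw <- paid_work_costs(cohort$works, cohort$work_days_per_month,
                        cohort$work_hours_per_day, cohort$days_missed,
                        cohort$hours_missed_5d, cohort$presenteeism_score,
                        uc$paid_work_hour_eur)
  ed <- early_departure_cost(cohort$on_pension,
                             cohort$pension_disability_level,
                             cohort$social_pension,
                             uc$paid_work_hour_eur,
                             uc$monthly_working_hours)
  ed <- apply_friction_period(ed, cohort$months_since_departure,
                              friction_days, uc$days_per_month)
  care <- care_costs(cohort$care_family_hpw, cohort$care_nonrelative_hpw,
                     cohort$care_professional_hpw,
                     uc$care_hour_eur, uc$weeks_per_month)
  dc <- direct_costs(cohort, uc)
  oop <- lapply(c(meds = "meds", diet = "diet", other = "other"), function(cat)
    out_of_pocket_valuation(cohort[[paste0("exp_", cat, "_low")]],
                            cohort[[paste0("exp_", cat, "_high")]]))
  cb <- data.frame(id = cohort$id,
                   hours_absent = pw$hours_absent,
                   hours_present = pw$hours_present,
                   absenteeism = pw$absenteeism,
                   presenteeism = pw$presenteeism,
                   early_departure = ed,
                   unpaid_work_loss = care$unpaid_work_loss,
                   informal_care = care$informal_care,
                   unpaid_uncompensated = care$unpaid_uncompensated,
                   direct_consult_public = dc$consult_public,
                   direct_consult_private = dc$consult_private,
                   direct_hospitalisation = dc$hospitalisation,
                   direct_treatment = dc$treatment,
                   oop_meds_mean = oop$meds$mean, oop_meds_min = oop$meds$min,
                   oop_meds_max = oop$meds$max,
                   oop_diet_mean = oop$diet$mean, oop_diet_min = oop$diet$min,
                   oop_diet_max = oop$diet$max,
                   oop_other_mean = oop$other$mean,
                   oop_other_min = oop$other$min,
                   oop_other_max = oop$other$max,
                   transfer_public = cohort$support_public,
                   transfer_private = cohort$support_private,
                   stringsAsFactors = FALSE)
  cb$total_indirect <- total_indirect(cb, include_early_departure)
  cb
}
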