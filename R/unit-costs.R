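## Monetary constants: unit-cost table loading and macro-level derivations.

#' Hourly unit cost of productivity loss at paid work
#'
#' Human capital valuation of an hour of paid work: annual GDP divided by the
#' number of employed persons and the maximum annual working hours, scaled by
#' the Cobb-Douglas output elasticity of labour (working time is not the only
#' factor of production).
#'
#' @param gdp annual GDP, EUR (not millions).
#' @param workers employed persons.
#' @param max_hours maximum working hours per person-year.
#' @param elasticity output elasticity of labour, in (0, 1].
#' @return EUR per hour (full precision; round to cents for reporting).
#' @export
#' @examples
#' round(derive_paid_work_unit_cost(420164.45e6, 16234e3, 2016, 0.65), 2) # 8.34
derive_paid_work_unit_cost <- function(gdp, workers, max_hours,
                                       elasticity = 0.65) {
  if (any(c(gdp, workers, max_hours, elasticity) <= 0) ||
      elasticity > 1 || anyNA(c(gdp, workers, max_hours, elasticity)))
    stop("all inputs must be positive (elasticity in (0, 1])")
  gdp / (workers * max_hours) * elasticity
}

#' Convert PLN amounts to EUR
#' @param amount_pln amount in PLN.
#' @param rate PLN per EUR exchange rate (> 0).
#' @export
convert_currency <- function(amount_pln, rate = 4.2624) {
  if (rate <= 0) stop("exchange rate must be positive")
  amount_pln / rate
}

#' Express a monthly cost as a share of monthly GDP per capita
#' @param cost EUR per month.
#' @param gdp_per_capita_annual annual GDP per capita, EUR.
#' @return percentage.
#' @export
#' @examples
#' gdp_share(462.47, 10900)  # ~50.9
gdp_share <- function(cost, gdp_per_capita_annual = 10900) {
  if (gdp_per_capita_annual <= 0) stop("GDP per capita must be positive")
  cost / (gdp_per_capita_annual / 12) * 100
}

#' Load the unit-cost table
#'
#' Reads the YAML unit-cost configuration (monetary constants, macro
#' parameters, drug dosing constants and sensitivity switches).  When
#' `paid_work_hour_eur` is null it is derived from the macro block via
#' [derive_paid_work_unit_cost()]; the `sensitivity$unit_cost_basis` switch
#' can replace it by a user-supplied per-hour value (`gdp_per_capita` basis
#' divides annual GDP per capita by the annual hours of a full-time worker).
#'
#' @param path YAML file; default is the packaged Poland 2015 table.
#' @param basis override for `sensitivity$unit_cost_basis`.
#' @return a `cd_unit_costs` list.
#' @export
unit_cost_table <- function(path = system.file("extdata",
                                               "unit_costs_poland.yaml",
                                               package = "cdburden"),
                            basis = NULL) {
  uc <- yaml::read_yaml(path)
  need <- c("pln_per_eur", "care_hour_eur", "monthly_working_hours",
            "weeks_per_month", "days_per_month", "direct", "drugs",
            "biologics")
  miss <- setdiff(need, names(uc))
  if (length(miss)) stop("unit-cost table lacks fields: ",
                         paste(miss, collapse = ", "))
  if (!is.null(basis)) uc$sensitivity$unit_cost_basis <- basis
  b <- uc$sensitivity$unit_cost_basis
  if (is.null(b)) b <- "gdp_per_worker_labour_share"
  uc$paid_work_hour_eur <- switch(
    b,
    gdp_per_worker_labour_share =
      if (is.null(uc$paid_work_hour_eur))
        derive_paid_work_unit_cost(uc$macro$gdp_million_eur * 1e6,
                                   uc$macro$employed_thousand * 1e3,
                                   uc$macro$max_annual_hours,
                                   uc$macro$labour_elasticity)
      else uc$paid_work_hour_eur,
    gdp_per_capita =
      uc$gdp_per_capita_annual_eur / uc$macro$max_annual_hours,
    average_wage = {
      if (is.null(uc$sensitivity$average_wage_hour_eur))
        stop("average_wage basis requires sensitivity$average_wage_hour_eur")
      uc$sensitivity$average_wage_hour_eur
    },
    gross_value_added = {
      if (is.null(uc$sensitivity$gross_value_added_hour_eur))
        stop("gross_value_added basis requires sensitivity$gross_value_added_hour_eur")
      uc$sensitivity$gross_value_added_hour_eur
    },
    stop("unknown unit-cost basis: ", b))
  bad <- c(uc$paid_work_hour_eur, uc$care_hour_eur,
           unlist(uc$direct, use.names = FALSE))
  if (any(bad < 0)) stop("monetary unit costs must be non-negative")
  class(uc) <- "cd_unit_costs"
  uc
}

#' Monthly drug cost per treatment flag
#'
#' DDD-based costing for oral drugs (`units_per_day` defined daily doses
#' times `days_per_month` times the unit cost) and recommended-dosing annual
#' totals divided by 12 for the biologics (weight-based where the schedule is
#' per kg).  Used by [direct_costs()]; exported for transparency.
#'
#' @param flag one of `aminosalicylate`, `immunosuppressant`,
#'   `glucocorticoid`, `adalimumab`, `infliximab`.
#' @param unit_costs a `cd_unit_costs` table.
#' @param body_weight kg, for weight-based dosing.
#' @return EUR per month of treatment (excluding biologic diagnostics).
#' @export
monthly_drug_cost <- function(flag, unit_costs = unit_cost_table(),
                              body_weight = unit_costs$biologics$body_weight_kg) {
  uc <- unit_costs
  if (flag %in% names(uc$drugs)) {
    d <- uc$drugs[[flag]]
    return(d$units_per_day * uc$days_per_month * d$unit_cost_eur)
  }
  if (flag == "adalimumab") {
    b <- uc$biologics$adalimumab
    return(b$mg_year_fixed / 12 / b$unit_mg * b$unit_cost_eur)
  }
  if (flag == "infliximab") {
    b <- uc$biologics$infliximab
    mg_year <- b$mg_per_kg_dose * body_weight * b$infusions_per_year
    return(mg_year / 12 / b$unit_mg * b$unit_cost_eur)
  }
  stop("treatment flag '", flag, "' not present in the unit-cost table")
}
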