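# cost engine: unit costs, productivity fractions, care, direct costs

test_that("paid-work unit cost derivation matches the quotient", {
  expect_equal(round(derive_paid_work_unit_cost(420164.45e6, 16234e3, 2016,
                                                0.65), 2), 8.34)
  expect_equal(round(derive_paid_work_unit_cost(420164.45e6, 16234e3, 2016,
                                                1), 2), 12.84)
  expect_error(derive_paid_work_unit_cost(0, 16234e3, 2016, 0.65), "positive")
  expect_error(derive_paid_work_unit_cost(1e9, 1e6, 2000, 1.2), "positive")
})

test_that("absenteeism fraction matches the day-grid oracle on a grid", {
  cases <- expand.grid(A_d = c(0, 1, 2, 5, 10, 21),
                       A_h = c(0, 1, 3, 7),
                       L_d = 21, L_h = 8)
  cases <- rbind(cases, data.frame(A_d = c(0, 3, 11), A_h = c(0, 2, 0),
                                   L_d = 11, L_h = c(6, 6, 6)))
  expect_gte(nrow(cases), 20)
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    expect_equal(absenteeism_fraction(cc$A_d, cc$A_h, cc$L_d, cc$L_h),
                 oracle_absence_fraction(cc$A_d, cc$A_h, cc$L_d, cc$L_h),
                 tolerance = 1e-12,
                 label = paste(unlist(cc), collapse = "/"))
  }
  expect_equal(absenteeism_fraction(0, 0, 21, 8), 0)
  expect_equal(absenteeism_fraction(21, 0, 21, 8), 1)
  expect_equal(absenteeism_fraction(2, 3, 21, 8), 27.4 / 168)
  expect_true(is.na(absenteeism_fraction(NA, 0, 21, 8)))
  expect_warning(r <- absenteeism_fraction(20, 45, 21, 8), "clamped")
  expect_lte(r, 1)
  expect_error(absenteeism_fraction(0, 0, 0, 8), "positive")
})

test_that("presenteeism fraction is a tenth of the score", {
  expect_equal(presenteeism_fraction(c(0, 4, 10)), c(0, 0.4, 1))
  expect_warning(r <- presenteeism_fraction(11), "missing")
  expect_true(is.na(r))
})

test_that("overall reduction composes the two fractions", {
  expect_equal(overall_reduction(1, 0.7), 1)
  expect_equal(overall_reduction(0, 0.4), 0.4)
  expect_equal(overall_reduction(27.4 / 168, 0.4),
               27.4 / 168 + (1 - 27.4 / 168) * 0.4)
  expect_error(overall_reduction(1.2, 0), "0, 1")
})

test_that("productivity fractions satisfy their invariants on random input", {
  set.seed(31)
  for (i in 1:200) {
    L_d <- sample(5:23, 1); L_h <- sample(4:10, 1)
    A_d <- sample(0:L_d, 1); A_h <- runif(1, 0, 5 * L_h / 4)
    sc <- sample(0:10, 1)
    ra <- absenteeism_fraction(A_d, A_h, L_d, L_h)
    rp <- presenteeism_fraction(sc)
    ro <- overall_reduction(ra, rp)
    expect_true(ra >= 0 && ra <= 1 && ro >= 0 && ro <= 1)
    expect_gte(ro, max(ra, rp) - 1e-12)
    # hours conservation: absent + presenteeism hours = monthly hours * R_O
    pw <- paid_work_costs(TRUE, L_d, L_h, A_d, A_h, sc, unit_cost = 1)
    expect_equal(pw$hours_absent + pw$hours_present, L_d * L_h * ro,
                 tolerance = 1e-9)
  }
})

test_that("paid-work costs match hand arithmetic and scale in the unit cost", {
  # full-time worker, 2 days + 3 single hours missed, presenteeism score 4
  pw <- paid_work_costs(TRUE, 21, 8, 2, 3, 4, unit_cost = 8.34)
  ra <- 27.4 / 168
  expect_equal(pw$absenteeism, 168 * ra * 8.34, tolerance = 1e-9)   # 228.52
  expect_equal(pw$presenteeism, (168 - 27.4) * 0.4 * 8.34, tolerance = 1e-9)
  expect_equal(round(pw$absenteeism, 2), 228.52)
  # degree-1 homogeneity in the unit cost (basis of the unit-cost sensitivity)
  pw2 <- paid_work_costs(TRUE, 21, 8, 2, 3, 4, unit_cost = 2 * 8.34)
  expect_equal(pw2$absenteeism, 2 * pw$absenteeism)
  expect_equal(pw2$presenteeism, 2 * pw$presenteeism)
  # non-workers contribute zeros; zero reductions cost nothing
  expect_equal(unlist(paid_work_costs(FALSE, NA, NA, NA, NA, NA, 8.34)),
               c(hours_absent = 0, hours_present = 0, absenteeism = 0,
                 presenteeism = 0))
  expect_equal(paid_work_costs(TRUE, 21, 8, 0, 0, 0, 8.34)$absenteeism, 0)
  # unspecified working time falls back to the full-time norm
  pw3 <- paid_work_costs(TRUE, NA, NA, 2, 3, 4, unit_cost = 8.34)
  expect_equal(pw3$absenteeism, pw$absenteeism)
})

test_that("early departure uses disability level, hours and unit cost", {
  expect_equal(early_departure_cost(TRUE, 0.75, FALSE, 8.34, 168),
               0.75 * 168 * 8.34)                       # 1050.84
  expect_equal(early_departure_cost(TRUE, NA, TRUE, 8.34, 168),
               1 * 168 * 8.34)                          # social pension: 100%
  expect_equal(early_departure_cost(FALSE, NA, FALSE, 8.34), 0)
  expect_true(is.na(early_departure_cost(TRUE, NA, FALSE, 8.34)))
})

test_that("friction period zeroes only departures older than the period", {
  expect_equal(apply_friction_period(1000, 24, friction_days = 90), 0)
  expect_equal(apply_friction_period(1000, 1, friction_days = 90), 1000)
  expect_equal(apply_friction_period(1000, 24, friction_days = NULL), 1000)
  expect_equal(apply_friction_period(1000, 24, friction_days = Inf), 1000)
  # boundary: 90 days is within the friction window
  expect_equal(apply_friction_period(1000, 90 / 30.44, friction_days = 90),
               1000)
  expect_warning(r <- apply_friction_period(1000, NA, friction_days = 90),
                 "retained")
  expect_equal(r, 1000)
  expect_error(apply_friction_period(-5, 1, 90), "non-negative")
})

test_that("care costs split replaced unpaid work into informal and paid parts", {
  cc <- care_costs(10, 0, 0)
  expect_equal(cc$unpaid_work_loss, 10 * 5.27 * 4.345)  # 228.98
  expect_equal(cc$informal_care, cc$unpaid_work_loss)
  expect_equal(cc$unpaid_uncompensated, 0)
  expect_equal(unlist(care_costs(0, 0, 0)),
               c(unpaid_work_loss = 0, informal_care = 0,
                 unpaid_uncompensated = 0))
  # oracle fixtures, including fractional hours and paid helpers
  set.seed(8)
  for (i in 1:25) {
    f <- round(runif(1, 0, 20), 1); nr <- round(runif(1, 0, 5), 1)
    p <- round(runif(1, 0, 8), 1)
    got <- care_costs(f, nr, p)
    want <- oracle_care(f, nr, p)
    expect_equal(unlist(got), want, tolerance = 1e-9, ignore_attr = TRUE)
    # decomposition identities
    expect_equal(got$informal_care + got$unpaid_uncompensated,
                 got$unpaid_work_loss, tolerance = 1e-9)
    expect_lte(got$informal_care, got$unpaid_work_loss + 1e-12)
  }
  expect_error(care_costs(-1, 0, 0), "non-negative")
})

test_that("out-of-pocket valuation uses midpoints and passes open amounts", {
  expect_equal(unlist(out_of_pocket_valuation(23.5, 46.9)),
               c(mean = 35.2, min = 23.5, max = 46.9))
  expect_equal(unlist(out_of_pocket_valuation(0, 23.5)),
               c(mean = 11.75, min = 0, max = 23.5))
  expect_equal(unlist(out_of_pocket_valuation(200, 200)),
               c(mean = 200, min = 200, max = 200))
  expect_error(out_of_pocket_valuation(50, 10), "exceeds")
})

test_that("direct costs follow the unit-cost table", {
  uc <- unit_cost_table()
  tc <- validate_cohort(toy_cohort())
  dc <- direct_costs(tc, uc)
  # respondent b: 2 consultations (1 private at 36), 1 medical hospitalisation
  expect_equal(dc$consult_public[2], 1 * 7.57)
  expect_equal(dc$consult_private[2], 36)
  expect_equal(dc$hospitalisation[2], 975.98)
  expect_equal(dc$treatment[2], 1 * 30.44 * 0.53)   # mesalazine DDDs
  # respondent a: no resource use at all
  expect_equal(unlist(dc[1, ]), c(consult_public = 0, consult_private = 0,
                                  hospitalisation = 0, treatment = 0))
  # drug costing building blocks
  expect_equal(monthly_drug_cost("aminosalicylate", uc), 30.44 * 0.53)
  expect_equal(monthly_drug_cost("adalimumab", uc), 1240 / 12 / 80 * 967.01)
  expect_equal(monthly_drug_cost("infliximab", uc),
               5 * 64.71 * 8 / 12 / 100 * 298.23)
  expect_error(monthly_drug_cost("aspirin", uc), "not present")
  # biologic users add the monthly diagnostics package
  tc$tx_adalimumab[1] <- TRUE
  dc2 <- direct_costs(tc, uc)
  expect_equal(dc2$treatment[1],
               monthly_drug_cost("adalimumab", uc) + 54.90)
  # hospitalisation mix: one-day + surgical + medical stays priced separately
  tc$hosp_count[3] <- 3L; tc$hosp_oneday_count[3] <- 1L
  tc$hosp_surgical[3] <- TRUE
  dc3 <- direct_costs(tc, uc)
  expect_equal(dc3$hospitalisation[3], 109.80 + 1553.16 + 975.98)
})

test_that("currency conversion and GDP-share normalisation", {
  expect_equal(convert_currency(4.2624), 1)
  expect_equal(convert_currency(0), 0)
  expect_equal(convert_currency(42.624), 10)
  expect_error(convert_currency(1, 0), "positive")
  expect_equal(round(gdp_share(462.47, 10900), 1), 50.9)
  expect_equal(gdp_share(0), 0)
  expect_equal(gdp_share(10900 / 12), 100)
})

test_that("total indirect cost adds the published component set", {
  cb <- data.frame(absenteeism = 10, presenteeism = 20,
                   unpaid_uncompensated = 1, informal_care = 5,
                   early_departure = 100)
  expect_equal(total_indirect(cb), 136)
  expect_equal(total_indirect(cb, include_early_departure = FALSE), 36)
  cb$presenteeism <- NA
  expect_true(is.na(total_indirect(cb)))
})

test_that("cost_cohort is consistent with its component functions", {
  ch <- generate_cohort(cohort_config(n = 100, seed = 17))
  uc <- unit_cost_table()
  cb <- cost_cohort(ch, uc)
  expect_equal(nrow(cb), nrow(ch))
  mon <- c("absenteeism", "presenteeism", "early_departure",
           "unpaid_work_loss", "informal_care", "unpaid_uncompensated")
  for (m in mon) expect_true(all(cb[[m]] >= 0, na.rm = TRUE), label = m)
  expect_true(all(cb$unpaid_uncompensated <= cb$unpaid_work_loss + 1e-9,
                  na.rm = TRUE))
  expect_equal(cb$total_indirect, total_indirect(cb), tolerance = 1e-12)
  i <- which(ch$works & !is.na(cb$absenteeism))[1]
  expect_equal(cb$absenteeism[i],
               ch$work_days_per_month[i] * ch$work_hours_per_day[i] *
                 absenteeism_fraction(ch$days_missed[i], ch$hours_missed_5d[i],
                                      ch$work_days_per_month[i],
                                      ch$work_hours_per_day[i]) *
                 uc$paid_work_hour_eur, tolerance = 1e-9)
})

test_that("alternative unit-cost bases rescale paid-work components", {
  p <- system.file("extdata", "unit_costs_poland.yaml", package = "cdburden")
  uc <- unit_cost_table(p)
  uc_cap <- unit_cost_table(p, basis = "gdp_per_capita")
  expect_equal(uc_cap$paid_work_hour_eur, 10900 / 2016)
  expect_error(unit_cost_table(p, basis = "average_wage"), "requires")
  ch <- generate_cohort(cohort_config(n = 60, seed = 23))
  cb1 <- cost_cohort(ch, uc)
  cb2 <- cost_cohort(ch, uc_cap)
  ratio <- uc_cap$paid_work_hour_eur / uc$paid_work_hour_eur
  expect_equal(cb2$absenteeism, cb1$absenteeism * ratio, tolerance = 1e-9)
  expect_equal(cb2$early_departure, cb1$early_departure * ratio,
               tolerance = 1e-9)
  # care components are valued at the wage, not the paid-work unit cost
  expect_equal(cb2$informal_care, cb1$informal_care)
})
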