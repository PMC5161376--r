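# Independent brute-force oracles.  Each recomputes a quantity by a route
# different from the implementation (enumeration, day-grid simulation, hand
# arithmetic) so the two can disagree.

# absenteeism fraction by walking the month's working days one by one
oracle_absence_fraction <- function(A_d, A_h, L_d, L_h) {
  lost <- 0
  for (day in seq_len(L_d)) {
    if (day <= A_d) lost <- lost + L_h       # a fully missed day
    else lost <- lost + A_h / 5              # average single hours per day
  }
  lost / (L_d * L_h)
}

# EQ-5D utility by looping over dimensions and levels, one decrement at a time
oracle_eq5d <- function(levels, vs) {
  dims <- c("mobility", "self_care", "usual", "pain", "anxiety")
  u <- vs$full_health_value
  if (any(levels > 1)) u <- u - vs$constant
  if (any(levels == 3)) u <- u - vs$n3
  for (j in seq_along(dims))
    for (l in 2:3)
      if (levels[j] == l) u <- u - vs$decrements[[paste0(dims[j], ":", l)]]
  u
}

# all 243 three-level five-dimension states
all_eq5d_states <- function() {
  as.matrix(expand.grid(m = 1:3, s = 1:3, u = 1:3, p = 1:3, a = 1:3))
}

# P-HBI by itemised hand summation
oracle_phbi <- function(wb, pain, stools, mass_present, comps_week,
                        include_mass = TRUE) {
  s <- wb + pain + stools + length(comps_week)
  if (include_mass && isTRUE(mass_present)) s <- s + 1
  s
}

# care costs by per-hour accumulation over the caregiver types
oracle_care <- function(fam, nonrel, prof, wage = 5.27, wpm = 4.345) {
  total <- 0; informal <- 0; uncomp <- 0
  for (h in seq_len(round(fam)))    { total <- total + 1; informal <- informal + 1 }
  for (h in seq_len(round(nonrel))) { total <- total + 1; informal <- informal + 1 }
  for (h in seq_len(round(prof)))   { total <- total + 1; uncomp <- uncomp + 1 }
  # fractional remainders
  total <- total + (fam - round(fam)) + (nonrel - round(nonrel)) +
    (prof - round(prof))
  informal <- informal + (fam - round(fam)) + (nonrel - round(nonrel))
  uncomp <- uncomp + (prof - round(prof))
  c(unpaid = total * wage * wpm, informal = informal * wage * wpm,
    uncomp = uncomp * wage * wpm)
}

# exact rank-sum p-value by enumeration of all group assignments (no ties)
oracle_ranksum_p <- function(x, g) {
  stopifnot(length(unique(x)) == length(x))
  r <- rank(x)
  n1 <- sum(g == levels(factor(g))[1])
  obs <- sum(r[g == levels(factor(g))[1]]) - n1 * (n1 + 1) / 2
  all_w <- apply(utils::combn(length(x), n1), 2,
                 function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- mean(all_w)
  mean(abs(all_w - mu) >= abs(obs - mu) - 1e-12)
}

# Cohen's kappa by hand from a confusion table
oracle_kappa <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# a tiny hand-written cohort with known values
toy_cohort <- function() {
  ch <- cdburden:::empty_cohort(3L)
  ch$id <- c("a", "b", "c")
  ch$age <- c(30, 45, 28)
  ch$sex <- c("female", "male", "female")
  ch$age_at_diagnosis <- c(22, 30, 25)
  ch$comorbidities <- c(FALSE, TRUE, FALSE)
  ch$phbi_wellbeing <- c(0L, 2L, 1L)
  ch$phbi_pain <- c(0L, 1L, 1L)
  ch$phbi_stools <- c(0L, 4L, 2L)
  ch$phbi_mass <- c("absent", "absent", "unknown")
  ch$phbi_comp_week <- c("", "arthralgia", "")
  ch$phbi_comp_earlier <- c("", "fistula", "")
  ch$eq_mobility <- c(1L, 2L, 1L)
  ch$eq_self_care <- c(1L, 1L, 1L)
  ch$eq_usual <- c(1L, 2L, 1L)
  ch$eq_pain <- c(1L, 2L, 2L)
  ch$eq_anxiety <- c(1L, 2L, 2L)
  ch$works <- c(TRUE, TRUE, FALSE)
  ch$student <- c(FALSE, FALSE, TRUE)
  ch$retired <- c(FALSE, FALSE, FALSE)
  ch$on_pension <- c(FALSE, FALSE, FALSE)
  ch$social_pension <- c(FALSE, FALSE, FALSE)
  ch$work_days_per_month <- c(21, 21, NA)
  ch$work_hours_per_day <- c(8, 8, NA)
  ch$days_missed <- c(0, 2, NA)
  ch$hours_missed_5d <- c(0, 3, NA)
  ch$presenteeism_score <- c(0L, 4L, NA)
  ch$impairment_score <- c(0L, 5L, 2L)
  ch$care_family_hpw <- c(0, 10, 0)
  ch$care_nonrelative_hpw <- c(0, 0, 0)
  ch$care_professional_hpw <- c(0, 0, 0)
  ch$consultations_total <- c(0L, 2L, 1L)
  ch$consultations_private <- c(0L, 1L, 0L)
  ch$private_consult_cost <- c(NA, 36, NA)
  ch$hosp_count <- c(0L, 1L, 0L)
  ch$hosp_days <- c(0, 5, 0)
  ch$hosp_oneday_count <- c(0L, 0L, 0L)
  ch$hosp_surgical <- c(FALSE, FALSE, FALSE)
  ch$tx_aminosalicylate <- c(FALSE, TRUE, FALSE)
  ch$tx_immunosuppressant <- c(FALSE, FALSE, FALSE)
  ch$tx_glucocorticoid <- c(FALSE, FALSE, FALSE)
  ch$tx_adalimumab <- c(FALSE, FALSE, FALSE)
  ch$tx_infliximab <- c(FALSE, FALSE, FALSE)
  ch$surgery_count <- c(0L, 1L, 0L)
  ch$months_since_last_surgery <- c(NA, 24, NA)
  ch$clinician_severity <- c("remission_or_mild", "moderate_or_severe",
                             "remission_or_mild")
  ch$exp_meds_low <- c(0, 23.5, 0)
  ch$exp_meds_high <- c(23.5, 46.9, 23.5)
  ch$exp_diet_low <- c(0, 0, 0)
  ch$exp_diet_high <- c(23.5, 23.5, 23.5)
  ch$exp_other_low <- c(0, 0, 0)
  ch$exp_other_high <- c(23.5, 23.5, 23.5)
  ch$support_public <- c(0, 0, 0)
  ch$support_private <- c(0, 50, 0)
  ch
}
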