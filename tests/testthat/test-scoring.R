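# P-HBI scoring, activity classification, EQ-5D utilities and norms

test_that("phbi_score sums the item map and honours the mass flag", {
  expect_equal(phbi_score(0, 0, 0, "absent", ""), 0L)
  expect_equal(phbi_score(2, 1, 4, "absent", "arthralgia"), 8L)
  expect_equal(phbi_score(2, 1, 4, "present", "arthralgia"), 9L)
  expect_equal(phbi_score(2, 1, 4, "present", "arthralgia",
                          include_mass = FALSE), 8L)
  expect_equal(phbi_score(2, 1, 4, "unknown", "arthralgia"), 8L)
  # unknown contributes 0 even when the mass item is included
  expect_equal(phbi_score(1, 1, 1, "unknown", ""),
               phbi_score(1, 1, 1, "absent", ""))
  # complications only count once each, earlier complications never count
  expect_equal(phbi_score(0, 0, 0, "absent", "fistula;abscess"), 2L)
  tc <- toy_cohort()
  expect_equal(phbi_score(tc), c(0L, 8L, 4L))
  # missing mandatory item
  expect_true(is.na(phbi_score(NA, 1, 1, "absent", "")))
  expect_true(is.na(phbi_score(1, 1, NA, "absent", "")))
})

test_that("phbi_score agrees with the hand-summation oracle and is monotone", {
  set.seed(42)
  for (i in 1:50) {
    wb <- sample(0:4, 1); pa <- sample(0:3, 1); st <- sample(0:12, 1)
    mp <- sample(c(TRUE, FALSE), 1)
    comps <- sample(phbi_complications(), sample(0:3, 1))
    got <- phbi_score(wb, pa, st, if (mp) "present" else "absent",
                      paste(comps, collapse = ";"))
    expect_equal(got, oracle_phbi(wb, pa, st, mp, comps))
    # adding a complication never lowers the score
    more <- setdiff(phbi_complications(), comps)
    if (length(more)) {
      got2 <- phbi_score(wb, pa, st, if (mp) "present" else "absent",
                         paste(c(comps, more[1]), collapse = ";"))
      expect_gte(got2, got)
    }
    # each item is monotone
    expect_gte(phbi_score(min(wb + 1, 4), pa, st, "absent", ""),
               phbi_score(wb, pa, st, "absent", ""))
  }
})

test_that("activity classification uses the >4 boundary", {
  expect_equal(as.character(classify_activity(c(0, 4, 5, 20, NA))),
               c("remission", "remission", "active", "active", NA))
})

test_that("with/without-mass classifications disagree only when mass scores", {
  set.seed(7)
  for (i in 1:100) {
    wb <- sample(0:4, 1); pa <- sample(0:3, 1); st <- sample(0:8, 1)
    mass <- sample(c("present", "absent", "unknown"), 1)
    s_with <- phbi_score(wb, pa, st, mass, "")
    s_without <- phbi_score(wb, pa, st, mass, "", include_mass = FALSE)
    disagree <- !identical(classify_activity(s_with),
                           classify_activity(s_without))
    if (disagree) expect_true(mass == "present" && s_without == 4)
  }
})

test_that("penetrating course looks at both time windows", {
  expect_true(penetrating_course("fistula", ""))
  expect_true(penetrating_course("", "fistula"))
  expect_true(penetrating_course("abscess;fistula", NA))
  expect_false(penetrating_course("abscess", "arthralgia"))
  expect_false(penetrating_course("", ""))
})

test_that("eq5d_utility equals the 243-state enumeration oracle", {
  states <- all_eq5d_states()
  for (vs_name in c("uk_mvh", "poland_synthetic")) {
    vs <- load_value_set(vs_name)
    got <- eq5d_utility(states[, 1], states[, 2], states[, 3], states[, 4],
                        states[, 5], value_set = vs)
    want <- apply(states, 1, oracle_eq5d, vs = vs)
    expect_equal(got, unname(want), tolerance = 1e-12)
    # full health anchors at 1; any single level-2 strictly lowers utility
    expect_equal(eq5d_utility(1, 1, 1, 1, 1, value_set = vs), 1)
    expect_true(all(got[rowSums(states > 1) > 0] < 1))
  }
})

test_that("eq5d_utility propagates missing levels and rejects bad levels", {
  vs <- load_value_set("uk_mvh")
  expect_true(is.na(eq5d_utility(1, NA, 1, 1, 1, value_set = vs)))
  expect_error(eq5d_utility(0, 1, 1, 1, 1, value_set = vs), "levels")
})

test_that("value sets anchor at full health with non-negative decrements", {
  for (vs_name in c("uk_mvh", "poland_synthetic")) {
    vs <- load_value_set(vs_name)
    expect_equal(vs$full_health_value, 1)
    expect_true(all(vs$decrements >= 0))
  }
})

test_that("norm lookup uses half-open age bands and flags uncovered ages", {
  norms <- load_population_norms("poland_synthetic")
  # inside a band
  expect_equal(matched_norm_utility(30, "male", norms),
               norms$utility[norms$sex == "male" & norms$age_low == 25])
  # boundary age belongs to the upper band: [25, 35) vs [35, 45)
  expect_equal(matched_norm_utility(35, "female", norms),
               norms$utility[norms$sex == "female" & norms$age_low == 35])
  expect_warning(u <- matched_norm_utility(115, "male", norms), "not covered")
  expect_true(is.na(u))
  # vectorised and NA-safe
  expect_equal(is.na(matched_norm_utility(c(20, NA), c("male", "male"),
                                          norms)), c(FALSE, TRUE))
})

test_that("score_cohort appends the scored columns coherently", {
  ch <- generate_cohort(cohort_config(n = 80, seed = 14))
  sc <- score_cohort(ch)
  expect_true(all(c("phbi_score", "activity", "penetrating", "utility",
                    "norm_utility") %in% names(sc)))
  expect_equal(as.character(sc$activity),
               as.character(classify_activity(sc$phbi_score)))
  expect_true(all(sc$utility <= 1, na.rm = TRUE))
})
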