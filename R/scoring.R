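## Disease-activity scoring (patient-completed Harvey-Bradshaw index) and
## EQ-5D-3L utility scoring against configurable value sets / norms.

#' Patient-completed Harvey-Bradshaw index score
#'
#' Sums the item scores of the patient version of the Harvey-Bradshaw index:
#' general well-being (0-4), abdominal pain (0-3), one point per liquid stool
#' per day, an abdominal-mass contribution, and one point per complication
#' present in the previous week.  Complications reported only *earlier* than
#' the previous week never contribute.  The self-report mass item is
#' trichotomous (present / absent / unknown); a `present` answer contributes
#' `mass_points` (default 1) when `include_mass = TRUE`, an `unknown` answer
#' contributes 0 (logged choice).  The three mandatory items (well-being,
#' pain, stools) must be present, otherwise the score is missing.
#'
#' All arguments are vectorised; a cohort `data.frame` can be passed as the
#' single first argument.
#'
#' @param wellbeing integer 0-4, or a canonical cohort `data.frame`.
#' @param pain integer 0-3.
#' @param stools liquid stools per day, >= 0.
#' @param mass `"present" | "absent" | "unknown"` (or `NA`).
#' @param comp_week `;`-separated complications present in the previous week.
#' @param include_mass include the abdominal-mass item (with/without variant).
#' @param mass_points points contributed by a `present` mass answer.
#' @return Integer score vector (`NA` where a mandatory item is missing).
#' @export
#' @examples
#' phbi_score(wellbeing = 2, pain = 1, stools = 4, mass = "absent",
#'            comp_week = "arthralgia")  # 8
phbi_score <- function(wellbeing, pain = NULL, stools = NULL, mass = NA,
                       comp_week = NA, include_mass = TRUE, mass_points = 1L) {
  if (is.data.frame(wellbeing)) {
    ch <- wellbeing
    return(phbi_score(ch$phbi_wellbeing, ch$phbi_pain, ch$phbi_stools,
                      ch$phbi_mass, ch$phbi_comp_week,
                      include_mass = include_mass, mass_points = mass_points))
  }
  n <- max(length(wellbeing), length(pain), length(stools))
  wellbeing <- rep_len(wellbeing, n); pain <- rep_len(pain, n)
  stools <- rep_len(stools, n); mass <- rep_len(as.character(mass), n)
  comp_week <- rep_len(as.character(comp_week), n)
  n_comp <- vapply(comp_week, function(s) {
    if (is.na(s)) 0L else length(intersect(split_tokens(s), phbi_complications()))
  }, integer(1), USE.NAMES = FALSE)
  mass_pts <- if (include_mass)
    ifelse(!is.na(mass) & mass == "present", mass_points, 0L) else 0L
  score <- wellbeing + pain + stools + mass_pts + n_comp
  as.integer(round(score))
}

#' Classify disease activity from a P-HBI score
#'
#' Active disease is a P-HBI of more than 4 points; 4 or fewer is remission.
#' Missing scores stay unclassified (`NA`) and are excluded from subgroup
#' analyses.
#'
#' @param score P-HBI score vector.
#' @return factor with levels `remission`, `active`.
#' @export
classify_activity <- function(score) {
  factor(ifelse(is.na(score), NA_character_,
                ifelse(score > 4, "active", "remission")),
         levels = c("remission", "active"))
}

#' Penetrating (fistulising) disease course
#'
#' `TRUE` iff a fistula is reported either in the previous week (P-HBI
#' complication item) or earlier (the additional question).
#'
#' @param comp_week,comp_earlier `;`-separated complication strings, or a
#'   cohort `data.frame` as the single first argument.
#' @export
penetrating_course <- function(comp_week, comp_earlier = NULL) {
  if (is.data.frame(comp_week)) {
    ch <- comp_week
    return(penetrating_course(ch$phbi_comp_week, ch$phbi_comp_earlier))
  }
  has_fistula <- function(s) vapply(as.character(s), function(x)
    !is.na(x) && "fistula" %in% split_tokens(x), logical(1), USE.NAMES = FALSE)
  has_fistula(comp_week) | has_fistula(comp_earlier)
}

#' Load an EQ-5D-3L value set
#'
#' A value set is a CSV with columns `dimension` (`mobility`, `self_care`,
#' `usual`, `pain`, `anxiety`, or the pseudo-dimensions `constant` for the
#' any-problem intercept and `n3` for the any-level-3 term), `level` (2 or 3;
#' ignored for pseudo-dimensions) and `decrement`.  Level-1 decrements are 0
#' by construction, so the state `11111` always scores
#' `full_health_value` (1).
#'
#' Two sets ship with the package: `"uk_mvh"`, the UK MVH A1 time trade-off
#' tariff, and `"poland_synthetic"`, a stand-in with the same N3 structure as
#' the Polish TTO tariff whose true coefficients are *not* packaged (see the
#' methods vignette); replace it with the real tariff file for substantive
#' Polish analyses.
#'
#' @param name packaged set name (`"uk_mvh"`, `"poland_synthetic"`) or a path
#'   to a CSV in the schema above.
#' @return A `cd_value_set` list: `name`, `full_health_value`, `decrements`
#'   (named numeric, names `dimension:level`), `constant`, `n3`.
#' @export
load_value_set <- function(name = "uk_mvh") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("eq5d3l_value_set_", name, ".csv"),
                package = "cdburden")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown value set: ", name)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("dimension", "level", "decrement") %in% names(tab)))
  dims <- c("mobility", "self_care", "usual", "pain", "anxiety")
  dec <- setNames(numeric(0), character(0))
  for (d in dims) for (l in 2:3) {
    v <- tab$decrement[tab$dimension == d & tab$level == l]
    dec[paste0(d, ":", l)] <- if (length(v)) v[1] else 0
  }
  vs <- list(name = if (file.exists(name)) basename(name) else name,
             full_health_value = 1,
             decrements = dec,
             constant = {
               v <- tab$decrement[tab$dimension == "constant"]
               if (length(v)) v[1] else 0
             },
             n3 = {
               v <- tab$decrement[tab$dimension == "n3"]
               if (length(v)) v[1] else 0
             })
  class(vs) <- "cd_value_set"
  vs
}

#' EQ-5D-3L utility index
#'
#' Utility of a 3-level five-dimension health state under a value set:
#' `1 - constant[any level > 1] - n3[any level == 3] - sum of per-dimension
#' decrements`.  Deterministic; a missing level gives a missing utility.
#'
#' @param mobility level 1-3, or a cohort `data.frame` (columns
#'   `eq_mobility` ... `eq_anxiety`) as the single first argument.
#' @param self_care,usual,pain,anxiety levels 1-3.
#' @param value_set a `cd_value_set` from [load_value_set()].
#' @return numeric utility vector.
#' @export
#' @examples
#' vs <- load_value_set("uk_mvh")
#' eq5d_utility(1, 1, 1, 1, 1, value_set = vs)  # 1
#' eq5d_utility(1, 1, 2, 2, 2, value_set = vs)
eq5d_utility <- function(mobility, self_care = NULL, usual = NULL, pain = NULL,
                         anxiety = NULL, value_set = load_value_set("uk_mvh")) {
  if (is.data.frame(mobility)) {
    ch <- mobility
    return(eq5d_utility(ch$eq_mobility, ch$eq_self_care, ch$eq_usual,
                        ch$eq_pain, ch$eq_anxiety, value_set = value_set))
  }
  stopifnot(inherits(value_set, "cd_value_set"))
  lv <- cbind(mobility, self_care, usual, pain, anxiety)
  if (any(lv < 1 | lv > 3, na.rm = TRUE))
    stop("EQ-5D levels must be 1, 2 or 3")
  dims <- c("mobility", "self_care", "usual", "pain", "anxiety")
  dec <- matrix(0, nrow(lv), 5)
  for (j in 1:5) for (l in 2:3)
    dec[, j] <- dec[, j] +
      ifelse(lv[, j] %in% l, value_set$decrements[paste0(dims[j], ":", l)], 0)
  any2 <- rowSums(lv > 1, na.rm = FALSE) > 0
  any3 <- rowSums(lv == 3, na.rm = FALSE) > 0
  u <- value_set$full_health_value -
    ifelse(any2, value_set$constant, 0) -
    ifelse(any3, value_set$n3, 0) -
    rowSums(dec)
  u[!complete.cases(lv)] <- NA_real_
  as.numeric(u)
}

#' Load a population-norms table
#'
#' Norms are mean utility indexes of the general population by age band and
#' sex: CSV columns `age_low`, `age_high`, `sex`, `utility`.  Bands are
#' half-open `[age_low, age_high)`.  The packaged `"poland_synthetic"` table
#' is a stand-in (the true Polish norms are not packaged; see the methods
#' vignette).
#'
#' @param name packaged table name or CSV path.
#' @export
load_population_norms <- function(name = "poland_synthetic") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("eq5d_norms_", name, ".csv"),
                package = "cdburden")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown norms table: ", name)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age_low", "age_high", "sex", "utility") %in% names(tab)))
  class(tab) <- c("cd_norms", class(tab))
  tab
}

#' Age- and sex-matched general-population utility
#'
#' Looks up the population-norm utility for each respondent's age band
#' (half-open `[age_low, age_high)`) and sex; ages not covered by the table
#' give `NA` with a warning.  The resulting paired series feeds the
#' signed-rank comparison of patients against the general population.
#'
#' @param age,sex respondent vectors.
#' @param norms a `cd_norms` table from [load_population_norms()].
#' @return numeric utility vector.
#' @export
matched_norm_utility <- function(age, sex, norms = load_population_norms()) {
  out <- rep(NA_real_, length(age))
  for (i in seq_along(age)) {
    if (is.na(age[i]) || is.na(sex[i])) next
    hit <- which(norms$sex == sex[i] & norms$age_low <= age[i] &
                   age[i] < norms$age_high)
    if (length(hit)) out[i] <- norms$utility[hit[1]]
  }
  if (anyNA(out[!is.na(age) & !is.na(sex)]))
    warning("some ages not covered by the norms table; set to NA")
  out
}

#' Score a cohort
#'
#' Appends the scored columns to a validated cohort: `phbi_score` (with the
#' abdominal-mass item as configured), `activity` (remission/active),
#' `penetrating`, `utility` and `norm_utility`.
#'
#' @param cohort canonical cohort `data.frame`.
#' @param value_set a `cd_value_set`.
#' @param norms a `cd_norms` table, or `NULL` to skip norm matching.
#' @param include_mass,mass_points see [phbi_score()].
#' @return the cohort with scored columns appended.
#' @export
score_cohort <- function(cohort, value_set = load_value_set("uk_mvh"),
                         norms = load_population_norms(),
                         include_mass = TRUE, mass_points = 1L) {
  cohort$phbi_score <- phbi_score(cohort, include_mass = include_mass,
                                  mass_points = mass_points)
  cohort$activity <- classify_activity(cohort$phbi_score)
  cohort$penetrating <- penetrating_course(cohort)
  cohort$utility <- eq5d_utility(cohort, value_set = value_set)
  if (!is.null(norms))
    cohort$norm_utility <- suppressWarnings(
      matched_norm_utility(cohort$age, cohort$sex, norms))
  cohort
}
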