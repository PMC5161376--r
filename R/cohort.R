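## Canonical cohort representation: one row per respondent, plain data.frame.
## All currency columns are EUR internally; PLN input is converted on read.

#' Column dictionary of the canonical cohort table
#'
#' Every cohort handled by the package is a plain `data.frame` with (a subset
#' of) these columns, one row per respondent.  Foreign files with different
#' headers are adapted through a column mapping (see [read_cohort()]).
#'
#' Set-valued answers (P-HBI complications, sources of financial support) are
#' stored as `;`-separated tokens.  Out-of-pocket expense answers are stored
#' as a `(low, high)` EUR pair per category: a predefined range keeps its two
#' bounds, an open amount above the top range is stored with `low == high`.
#'
#' @return A `data.frame` with columns `name`, `type`
#'   (`"numeric"|"integer"|"logical"|"character"`), `role` and `description`.
#' @export
#' @examples
#' head(cohort_columns())
cohort_columns <- function() {
  spec <- list(
    # name,                     type,        role,        description
    c("id",                     "character", "meta",      "opaque respondent identifier"),
    c("age",                    "numeric",   "demog",     "current age, years (adults only: >= 18)"),
    c("sex",                    "character", "demog",     "male | female"),
    c("residence",              "character", "demog",     "place of residence category"),
    c("age_at_diagnosis",       "numeric",   "demog",     "age at CD diagnosis, years"),
    c("comorbidities",          "logical",   "demog",     "any comorbidity present"),
    c("tx_aminosalicylate",     "logical",   "treatment", "current mesalazine/sulfasalazine"),
    c("tx_immunosuppressant",   "logical",   "treatment", "current azathioprine/mercaptopurine/methotrexate"),
    c("tx_glucocorticoid",      "logical",   "treatment", "current budesonide/prednisone/prednisolone/methylprednisolone"),
    c("tx_adalimumab",          "logical",   "treatment", "current adalimumab"),
    c("tx_infliximab",          "logical",   "treatment", "current infliximab"),
    c("surgery_count",          "integer",   "history",   "number of CD surgeries since diagnosis"),
    c("months_since_last_surgery", "numeric", "history",  "months since last CD surgery"),
    c("clinician_severity",     "character", "history",   "last clinical assessment: remission_or_mild | moderate_or_severe | unknown"),
    c("phbi_wellbeing",         "integer",   "phbi",      "general well-being item, 0-4"),
    c("phbi_pain",              "integer",   "phbi",      "abdominal pain item, 0-3"),
    c("phbi_stools",            "integer",   "phbi",      "liquid stools per day, >= 0"),
    c("phbi_mass",              "character", "phbi",      "abdominal mass: present | absent | unknown"),
    c("phbi_comp_week",         "character", "phbi",      "complications in the previous week, ;-separated"),
    c("phbi_comp_earlier",      "character", "phbi",      "complications earlier than the previous week, ;-separated"),
    c("eq_mobility",            "integer",   "eq5d",      "EQ-5D-3L mobility level 1-3"),
    c("eq_self_care",           "integer",   "eq5d",      "EQ-5D-3L self-care level 1-3"),
    c("eq_usual",               "integer",   "eq5d",      "EQ-5D-3L usual activities level 1-3"),
    c("eq_pain",                "integer",   "eq5d",      "EQ-5D-3L pain/discomfort level 1-3"),
    c("eq_anxiety",             "integer",   "eq5d",      "EQ-5D-3L anxiety/depression level 1-3"),
    c("works",                  "logical",   "work",      "any occupational activity"),
    c("student",                "logical",   "work",      "student status"),
    c("retired",                "logical",   "work",      "retired"),
    c("on_pension",             "logical",   "work",      "on social or disability pension due to CD"),
    c("pension_disability_level", "numeric", "work",      "registered inability to work, fraction 0-1 (1 assumed for social pension)"),
    c("months_since_departure", "numeric",   "work",      "months since registered departure from the labour market"),
    c("social_pension",         "logical",   "work",      "social (not disability) pension recipient"),
    c("work_days_per_month",    "numeric",   "work",      "L_d: maximum working days per month"),
    c("work_hours_per_day",     "numeric",   "work",      "L_h: maximum working hours per day"),
    c("days_missed",            "numeric",   "work",      "A_d: full days missed from paid work in the last month"),
    c("hours_missed_5d",        "numeric",   "work",      "A_h: single hours missed in the last 5 working days"),
    c("presenteeism_score",     "integer",   "work",      "impact on productivity at paid work, 0 (none) - 10 (completely prevented)"),
    c("impairment_score",       "integer",   "care",      "impact on usual activities, 0-10"),
    c("care_family_hpw",        "numeric",   "care",      "unpaid assistance from family, hours/week"),
    c("care_nonrelative_hpw",   "numeric",   "care",      "unpaid assistance from non-relatives, hours/week"),
    c("care_professional_hpw",  "numeric",   "care",      "professional or paid assistance, hours/week"),
    c("consultations_total",    "integer",   "resource",  "specialist consultations in the last month (public + private)"),
    c("consultations_private",  "integer",   "resource",  "privately financed consultations in the last month"),
    c("private_consult_cost",   "numeric",   "resource",  "average cost of a private consultation, EUR"),
    c("hosp_count",             "integer",   "resource",  "hospital stays in the last month (one-day included)"),
    c("hosp_days",              "numeric",   "resource",  "total length of hospital stays, days"),
    c("hosp_oneday_count",      "integer",   "resource",  "one-day hospitalisations among the stays"),
    c("hosp_surgical",          "logical",   "resource",  "any surgical hospitalisation in the last month"),
    c("exp_meds_low",           "numeric",   "expense",   "out-of-pocket medicines, range low bound, EUR/month"),
    c("exp_meds_high",          "numeric",   "expense",   "out-of-pocket medicines, range high bound, EUR/month"),
    c("exp_diet_low",           "numeric",   "expense",   "diet/equipment/transport, low bound, EUR/month"),
    c("exp_diet_high",          "numeric",   "expense",   "diet/equipment/transport, high bound, EUR/month"),
    c("exp_other_low",          "numeric",   "expense",   "information/hygiene/other, low bound, EUR/month"),
    c("exp_other_high",         "numeric",   "expense",   "information/hygiene/other, high bound, EUR/month"),
    c("support_public",         "numeric",   "transfer",  "benefits from public institutions, EUR/month"),
    c("support_private",        "numeric",   "transfer",  "support from relatives/NGOs, EUR/month"),
    c("support_sources",        "character", "transfer",  "support sources, ;-separated tokens")
  )
  out <- as.data.frame(do.call(rbind, spec), stringsAsFactors = FALSE)
  names(out) <- c("name", "type", "role", "description")
  out
}

#' @rdname cohort_columns
#' @export
currency_columns <- function() {
  c("private_consult_cost", "exp_meds_low", "exp_meds_high", "exp_diet_low",
    "exp_diet_high", "exp_other_low", "exp_other_high",
    "support_public", "support_private")
}

#' Complication tokens recognised in P-HBI complication sets
#' @export
phbi_complications <- function() {
  c("arthralgia", "uveitis", "erythema_nodosum", "aphthous_ulcers",
    "pyoderma_gangrenosum", "anal_fissure", "fistula", "abscess")
}

empty_cohort <- function(n = 0L) {
  dict <- cohort_columns()
  cols <- lapply(dict$type, function(t)
    switch(t,
           numeric   = rep(NA_real_, n),
           integer   = rep(NA_integer_, n),
           logical   = rep(NA, n),
           character = rep(NA_character_, n)))
  names(cols) <- dict$name
  as.data.frame(cols, stringsAsFactors = FALSE)
}

coerce_column <- function(x, type) {
  if (type == "character") return(as.character(x))
  x_chr <- trimws(as.character(x))
  x_chr[x_chr %in% c("", "NA", "na", ".")] <- NA_character_
  out <- switch(type,
                numeric = suppressWarnings(as.numeric(x_chr)),
                integer = suppressWarnings(as.integer(round(as.numeric(x_chr)))),
                logical = {
                  lo <- tolower(x_chr)
                  ifelse(lo %in% c("true", "t", "1", "yes", "y"), TRUE,
                         ifelse(lo %in% c("false", "f", "0", "no", "n"), FALSE, NA))
                })
  out
}

#' Read a cohort file into the canonical table
#'
#' Reads a delimited text file (or, with `readxl` installed, an XLSX sheet),
#' renames columns through an optional mapping, coerces each column to its
#' dictionary type (unparseable cells become `NA`, never a failed row),
#' converts PLN currency columns to EUR, and applies [validate_cohort()].
#'
#' @param path file to read (CSV with header, or `.xlsx`).
#' @param mapping optional named character vector or YAML file path mapping
#'   canonical names to the file's column names, e.g.
#'   `c(age = "wiek", sex = "plec")`.
#' @param currency `"EUR"` (default) or `"PLN"`; PLN monetary columns are
#'   divided by `pln_per_eur` on read.
#' @param pln_per_eur exchange rate used when `currency = "PLN"`.
#' @param validate apply the plausibility rules after reading.
#' @return A canonical cohort `data.frame`; validation notes (if any) in
#'   `attr(, "validation_notes")`.
#' @seealso [cohort_columns()], [validate_cohort()], [write_cohort()]
#' @export
read_cohort <- function(path, mapping = NULL, currency = c("EUR", "PLN"),
                        pln_per_eur = 4.2624, validate = TRUE) {
  currency <- match.arg(currency)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character")
  }
  if (nrow(raw) == 0L) {
    warning("empty cohort file: ", path)
    return(empty_cohort(0L))
  }
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
    mapping <- unlist(yaml::read_yaml(mapping))
  if (!is.null(mapping)) {
    hit <- match(mapping, names(raw))
    for (i in seq_along(mapping))
      if (!is.na(hit[i])) names(raw)[hit[i]] <- names(mapping)[i]
  }
  dict <- cohort_columns()
  unknown <- setdiff(names(raw), dict$name)
  if (length(unknown))
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "))
  out <- empty_cohort(nrow(raw))
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[i]
    if (nm %in% names(raw)) out[[nm]] <- coerce_column(raw[[nm]], dict$type[i])
  }
  if (currency == "PLN")
    for (nm in currency_columns())
      out[[nm]] <- convert_currency(out[[nm]], pln_per_eur)
  if (all(is.na(out$id))) out$id <- sprintf("R%04d", seq_len(nrow(out)))
  # retain any record with at least one substantive answer
  answered <- rowSums(!is.na(out[setdiff(names(out), "id")])) > 0L
  if (any(!answered)) {
    warning(sum(!answered), " record(s) without any answer dropped")
    out <- out[answered, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (validate) out <- validate_cohort(out) else out
}

#' Write a canonical cohort table to CSV
#'
#' Inverse of [read_cohort()] for the retained fields (round-trip identity on
#' validated cohorts).
#' @param cohort canonical cohort `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort[, intersect(cohort_columns()$name, names(cohort))],
            path, row.names = FALSE, na = "")
  invisible(path)
}

note_df <- function(row = integer(), id = character(), field = character(),
                    reason = character()) {
  data.frame(row = as.integer(row), id = as.character(id),
             field = as.character(field), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

#' Apply plausibility rules to a cohort
#'
#' Internally inconsistent answers are replaced by missing values (never by
#' dropping the respondent), and each replacement is logged.  The rules are
#' idempotent: validating a validated cohort changes nothing and produces no
#' new notes.  Rules include: age at diagnosis above current age; full days
#' missed exceeding the monthly working time; single hours missed exceeding
#' five working days; private consultations exceeding total consultations;
#' a disability level without a pension; out-of-range item scores, EQ-5D
#' levels or probabilities; negative hours, counts or amounts.
#'
#' @param cohort canonical cohort `data.frame`.
#' @param verbose emit a message per replacement.
#' @return The cohort with offending cells set `NA`; the log in
#'   `attr(, "validation_notes")` (columns `row`, `id`, `field`, `reason`).
#' @export
validate_cohort <- function(cohort, verbose = FALSE) {
  notes <- note_df()
  flag <- function(idx, field, reason) {
    idx <- which(idx %in% TRUE)
    if (length(idx))
      notes <<- rbind(notes, note_df(idx, cohort$id[idx], field, reason))
    idx
  }
  blank <- function(idx, field) if (length(idx)) cohort[[field]][idx] <<- NA

  # age is kept (the row is only flagged); inclusion filtering is a pipeline step
  flag(cohort$age < 18, "age",
       "below adult inclusion age (respondent flagged, excluded from study analyses)")

  blank(flag(cohort$age_at_diagnosis > cohort$age, "age_at_diagnosis",
             "age at diagnosis higher than current age"), "age_at_diagnosis")
  blank(flag(cohort$days_missed > cohort$work_days_per_month, "days_missed",
             "absolute productivity reduction exceeds monthly working time"),
        "days_missed")
  blank(flag(cohort$hours_missed_5d > 5 * cohort$work_hours_per_day,
             "hours_missed_5d",
             "single hours missed exceed five working days"), "hours_missed_5d")
  bad_cons <- flag(cohort$consultations_private > cohort$consultations_total,
                   "consultations_private",
                   "private consultations exceed total consultations")
  blank(bad_cons, "consultations_private")
  blank(bad_cons, "consultations_total")
  blank(flag(!is.na(cohort$pension_disability_level) &
               !(cohort$on_pension %in% TRUE), "pension_disability_level",
             "disability level reported without a pension"),
        "pension_disability_level")
  blank(flag(cohort$pension_disability_level < 0 |
               cohort$pension_disability_level > 1, "pension_disability_level",
             "disability level outside [0, 1]"), "pension_disability_level")
  blank(flag(!is.na(cohort$months_since_last_surgery) &
               (cohort$surgery_count %in% 0L), "months_since_last_surgery",
             "time since surgery reported without any surgery"),
        "months_since_last_surgery")
  blank(flag(cohort$hosp_oneday_count > cohort$hosp_count, "hosp_oneday_count",
             "one-day stays exceed total hospitalisations"), "hosp_oneday_count")

  for (f in c("presenteeism_score", "impairment_score"))
    blank(flag(cohort[[f]] < 0 | cohort[[f]] > 10, f,
               "score outside the 0-10 scale"), f)
  blank(flag(cohort$phbi_wellbeing < 0 | cohort$phbi_wellbeing > 4,
             "phbi_wellbeing", "well-being item outside 0-4"), "phbi_wellbeing")
  blank(flag(cohort$phbi_pain < 0 | cohort$phbi_pain > 3, "phbi_pain",
             "pain item outside 0-3"), "phbi_pain")
  for (f in c("eq_mobility", "eq_self_care", "eq_usual", "eq_pain", "eq_anxiety"))
    blank(flag(!(cohort[[f]] %in% c(1L, 2L, 3L)) & !is.na(cohort[[f]]), f,
               "EQ-5D level outside 1-3"), f)
  nonneg <- c("phbi_stools", "days_missed", "hours_missed_5d",
              "work_days_per_month", "work_hours_per_day", "surgery_count",
              "months_since_last_surgery", "months_since_departure",
              "care_family_hpw", "care_nonrelative_hpw", "care_professional_hpw",
              "consultations_total", "consultations_private",
              "private_consult_cost", "hosp_count", "hosp_days",
              "hosp_oneday_count", "support_public", "support_private",
              currency_columns())
  for (f in unique(nonneg))
    blank(flag(cohort[[f]] < 0, f, "negative value"), f)
  for (cat in c("meds", "diet", "other")) {
    lo <- paste0("exp_", cat, "_low"); hi <- paste0("exp_", cat, "_high")
    bad <- flag(cohort[[lo]] > cohort[[hi]], lo,
                "expense range low bound exceeds high bound")
    blank(bad, lo); blank(bad, hi)
  }
  # normalise categorical codings; unrecognised values -> NA
  sx <- tolower(cohort$sex)
  blank(flag(!is.na(sx) & !sx %in% c("male", "female"), "sex",
             "unrecognised sex code"), "sex")
  cohort$sex <- ifelse(tolower(cohort$sex) %in% c("male", "female"),
                       tolower(cohort$sex), cohort$sex)
  ms <- tolower(cohort$phbi_mass)
  blank(flag(!is.na(ms) & !ms %in% c("present", "absent", "unknown"),
             "phbi_mass", "unrecognised abdominal-mass code"), "phbi_mass")
  for (f in c("phbi_comp_week", "phbi_comp_earlier")) {
    cleaned <- vapply(cohort[[f]], function(s) {
      if (is.na(s) || !nzchar(s)) return(s)
      tok <- unique(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
      paste(tok[tok %in% phbi_complications()], collapse = ";")
    }, character(1), USE.NAMES = FALSE)
    changed <- !is.na(cohort[[f]]) & cleaned != cohort[[f]]
    flag(changed, f, "duplicate or unrecognised complication tokens removed")
    cohort[[f]] <- cleaned
  }
  if (verbose && nrow(notes))
    for (i in seq_len(nrow(notes)))
      message(sprintf("validate: row %d (%s) %s: %s", notes$row[i],
                      notes$id[i], notes$field[i], notes$reason[i]))
  attr(cohort, "validation_notes") <- notes
  cohort
}

#' @rdname validate_cohort
#' @export
validation_notes <- function(cohort) {
  n <- attr(cohort, "validation_notes")
  if (is.null(n)) note_df() else n
}

split_tokens <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0)
  else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
}
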