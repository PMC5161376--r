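## End-to-end orchestration: read or generate -> validate -> score -> cost ->
## compare, writing a reviewable bundle of plain CSV tables plus a manifest.

#' Run configuration for the analysis pipeline
#'
#' Exactly one input source: a cohort file (`input`) or the synthetic
#' generator (`synthetic = TRUE`, with `generator` options passed to
#' [cohort_config()]).
#'
#' @param input path to a cohort file, or `NULL` for a synthetic cohort.
#' @param synthetic generate the cohort instead of reading it.
#' @param generator list of [cohort_config()] arguments for synthetic input.
#' @param mapping optional column mapping for foreign files.
#' @param unit_costs path to a unit-cost YAML (default: packaged table).
#' @param value_set,norms names/paths for [load_value_set()] /
#'   [load_population_norms()].
#' @param include_mass score the P-HBI with the abdominal-mass item.
#' @param friction_days friction period (days) for early departure, or
#'   `NULL` for the pure human capital approach.
#' @param unit_cost_basis sensitivity switch, see [unit_cost_table()].
#' @param covariates adjustment set for the subgroup models.  The default is
#'   the reduced set used for the cost tables; `covariates_full` adds sex
#'   and pension status.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the synthetic source.
#' @return a `cd_run_config` list.
#' @export
run_config <- function(input = NULL, synthetic = is.null(input),
                       generator = list(), mapping = NULL,
                       unit_costs = NULL, value_set = "uk_mvh",
                       norms = "poland_synthetic", include_mass = TRUE,
                       friction_days = NULL,
                       unit_cost_basis = NULL,
                       covariates = c("age", "age_at_diagnosis",
                                      "comorbidities", "surgery"),
                       out_dir = "cdburden_out", seed = 1L) {
  if (is.null(input) && !synthetic)
    stop("exactly one input source required: a file or the generator")
  if (!is.null(input) && synthetic)
    stop("exactly one input source required, not both")
  cfg <- as.list(environment())
  class(cfg) <- "cd_run_config"
  cfg
}

covariate_frame <- function(cohort) {
  data.frame(age = cohort$age,
             age_at_diagnosis = cohort$age_at_diagnosis,
             comorbidities = as.numeric(cohort$comorbidities %in% TRUE),
             surgery = as.numeric(cohort$surgery_count > 0),
             sex = as.numeric(cohort$sex == "male"),
             pension = as.numeric(cohort$on_pension %in% TRUE))
}

#' Box-whisker numeric summaries per subgroup
#'
#' The numeric content of the box-whisker displays: per subgroup and
#' outcome the minimum, 5th percentile, quartiles, median, 95th percentile,
#' maximum and mean.  Empty subgroups are omitted with a note attribute.
#'
#' @param data `data.frame` with the outcomes and a `group` column.
#' @param outcomes outcome column names.
#' @param group grouping column (default `activity`).
#' @return long `data.frame`: one row per (outcome, subgroup).
#' @export
summarize_figures <- function(data, outcomes, group = "activity") {
  groups <- c(list(all = rep(TRUE, nrow(data))),
              lapply(setNames(nm = levels(factor(data[[group]]))),
                     function(l) data[[group]] %in% l))
  out <- NULL; omitted <- character(0)
  for (oc in outcomes) for (g in names(groups)) {
    x <- data[[oc]][groups[[g]]]
    d <- describe(x)
    if (d$n == 0L) { omitted <- c(omitted, paste(oc, g)); next }
    out <- rbind(out, cbind(outcome = oc, subgroup = g, d))
  }
  attr(out, "omitted") <- omitted
  out
}

write_table <- function(df, dir, name) {
  p <- file.path(dir, paste0(name, ".csv"))
  write.csv(df, p, row.names = FALSE, na = "")
  p
}

#' Run the full analysis pipeline
#'
#' Reads or generates a cohort, validates and scores it, computes the
#' per-patient cost breakdown, assembles the study-style summary tables
#' (participant characteristics, EQ-5D response frequencies, indirect costs
#' by severity with adjusted contrasts, cost components) and the statistics
#' table, and writes everything as CSV plus a JSON run manifest.  Identical
#' configuration and seed give byte-identical numeric output.
#'
#' @param config a `cd_run_config` from [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory objects (`cohort`, `costs`,
#'   `tables`, `stats`, `paths`).
#' @export
run_pipeline <- function(config = run_config(), quiet = TRUE) {
  stopifnot(inherits(config, "cd_run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  uc <- if (is.null(config$unit_costs)) unit_cost_table(basis = config$unit_cost_basis)
  else unit_cost_table(config$unit_costs, basis = config$unit_cost_basis)
  vs <- load_value_set(config$value_set)
  nm <- if (is.null(config$norms)) NULL else load_population_norms(config$norms)

  say("input")
  cohort <- if (config$synthetic) {
    gen <- do.call(cohort_config, modifyList(list(seed = config$seed),
                                             config$generator))
    generate_cohort(gen)
  } else {
    read_cohort(config$input, mapping = config$mapping)
  }
  cohort <- cohort[is.na(cohort$age) | cohort$age >= 18, , drop = FALSE]

  say("score")
  sc <- score_cohort(cohort, value_set = vs, norms = nm,
                     include_mass = config$include_mass)
  say("cost")
  cb <- cost_cohort(sc, uc, friction_days = config$friction_days)

  # --- summary tables ------------------------------------------------------
  act <- sc$activity
  strata <- list(all = rep(TRUE, nrow(sc)), remission = act %in% "remission",
                 active = act %in% "active")
  chr <- do.call(rbind, lapply(names(strata), function(g) {
    i <- strata[[g]]
    data.frame(subgroup = g, n = sum(i),
               age_mean = mean(sc$age[i], na.rm = TRUE),
               male_pct = 100 * mean(sc$sex[i] == "male", na.rm = TRUE),
               phbi_mean = mean(sc$phbi_score[i], na.rm = TRUE),
               works_pct = 100 * mean(sc$works[i], na.rm = TRUE),
               pension_pct = 100 * mean(sc$on_pension[i], na.rm = TRUE),
               student_pct = 100 * mean(sc$student[i], na.rm = TRUE),
               penetrating_pct = 100 * mean(sc$penetrating[i], na.rm = TRUE))
  }))
  eqf <- do.call(rbind, lapply(
    c(mobility = "eq_mobility", self_care = "eq_self_care",
      usual = "eq_usual", pain = "eq_pain", anxiety = "eq_anxiety"),
    function(cn) do.call(rbind, lapply(names(strata), function(g) {
      lv <- factor(sc[[cn]][strata[[g]]], levels = 1:3)
      n <- sum(!is.na(lv))
      data.frame(dimension = sub("eq_", "", cn), subgroup = g, n = n,
                 no_problems_pct = 100 * mean(lv == 1, na.rm = TRUE),
                 some_problems_pct = 100 * mean(lv == 2, na.rm = TRUE),
                 severe_problems_pct = 100 * mean(lv == 3, na.rm = TRUE))
    }))))

  comp_cols <- c("absenteeism", "early_departure", "presenteeism",
                 "unpaid_uncompensated", "informal_care", "unpaid_work_loss",
                 "direct_consult_public", "direct_consult_private",
                 "direct_hospitalisation", "direct_treatment",
                 "oop_meds_mean", "oop_diet_mean", "oop_other_mean",
                 "transfer_public", "transfer_private", "total_indirect")
  components <- do.call(rbind, lapply(comp_cols, function(cc) {
    d <- describe(cb[[cc]])
    cbind(component = cc, d,
          gdp_share_pct = gdp_share(d$mean, uc$gdp_per_capita_annual_eur))
  }))

  # model frame: numeric covariates + group + cost outcomes (names disjoint)
  merged <- cbind(covariate_frame(sc), cb[setdiff(names(cb), "id")])
  merged$utility <- sc$utility
  merged$group <- act
  by_sev <- NULL; contrasts <- NULL
  if (all(table(act) >= 10)) {
    for (cc in c("absenteeism", "presenteeism", "unpaid_uncompensated",
                 "informal_care", "total_indirect")) {
      for (g in c("remission", "active")) {
        d <- describe(cb[[cc]][act %in% g])
        by_sev <- rbind(by_sev, cbind(component = cc, subgroup = g, d))
      }
      # components with almost no positive costs may be inestimable at small
      # n; they are dropped from the contrast table rather than reported badly
      fitok <- tryCatch(
        suppressWarnings(two_part_cost_model(merged, cc, "group",
                                             config$covariates)),
        error = function(e) NULL)
      if (!is.null(fitok))
        contrasts <- rbind(contrasts, data.frame(
          component = cc,
          mean_remission = fitok$adjusted_means[["remission"]],
          mean_active = fitok$adjusted_means[["active"]],
          difference = fitok$difference, ci_low = fitok$ci_low,
          ci_high = fitok$ci_high, p = fitok$p_value, n = fitok$n))
    }
    ufit <- tryCatch(
      suppressWarnings(fractional_logit_means(
        within(merged, utility01 <- pmin(pmax(utility, 0), 1)),
        "utility01", "group", c(config$covariates, "sex", "pension"))),
      error = function(e) NULL)
    if (!is.null(ufit))
      contrasts <- rbind(contrasts, data.frame(
        component = "utility", mean_remission = ufit$adjusted_means[["remission"]],
        mean_active = ufit$adjusted_means[["active"]],
        difference = ufit$difference, ci_low = ufit$ci_low,
        ci_high = ufit$ci_high, p = ufit$p_value, n = ufit$n))
  }

  say("statistics")
  stats_tab <- rbind(
    cbind(statistic = "spearman_utility_phbi",
          spearman_rho(sc$utility, sc$phbi_score)[c("rho", "n", "p")]),
    cbind(statistic = "spearman_impairment_phbi",
          setNames(spearman_rho(sc$impairment_score, sc$phbi_score)[
            c("rho", "n", "p")], c("rho", "n", "p"))))
  names(stats_tab)[2] <- "estimate"
  ag <- agreement(as.character(sc$activity),
                  ifelse(sc$clinician_severity == "unknown", NA,
                         ifelse(sc$clinician_severity == "moderate_or_severe",
                                "active", "remission")))
  stats_tab <- rbind(stats_tab,
                     data.frame(statistic = "kappa_activity_clinician",
                                estimate = ag$kappa, n = ag$n, p = ag$p),
                     data.frame(statistic = "percent_agreement",
                                estimate = ag$percent_agreement, n = ag$n,
                                p = NA_real_))
  if (!is.null(sc$norm_utility)) {
    sr <- group_tests(sc$utility, sc$norm_utility, type = "signedrank")
    stats_tab <- rbind(stats_tab,
                       data.frame(statistic = "signedrank_utility_vs_norms",
                                  estimate = sr$statistic, n = sr$n, p = sr$p))
  }

  monthly_hours <- sc$work_days_per_month * sc$work_hours_per_day
  fig_data <- data.frame(
    activity = act,
    utility = sc$utility,
    impairment_score = sc$impairment_score,
    reduction_absenteeism = ifelse(sc$works %in% TRUE,
                                   cb$hours_absent / monthly_hours, NA),
    reduction_overall = ifelse(sc$works %in% TRUE,
                               (cb$hours_absent + cb$hours_present) /
                                 monthly_hours, NA))
  figs <- summarize_figures(
    fig_data, c("utility", "reduction_absenteeism", "reduction_overall",
                "impairment_score"))

  paths <- c(
    cohort = write_table(sc, config$out_dir, "cohort_scored"),
    costs = write_table(cb, config$out_dir, "cost_breakdown"),
    characteristics = write_table(chr, config$out_dir, "table_characteristics"),
    eq5d = write_table(eqf, config$out_dir, "table_eq5d_frequencies"),
    components = write_table(components, config$out_dir,
                             "table_cost_components"),
    stats = write_table(stats_tab, config$out_dir, "statistics"),
    figures = write_table(figs, config$out_dir, "figure_summaries"))
  if (!is.null(by_sev))
    paths["by_severity"] <- write_table(by_sev, config$out_dir,
                                        "table_costs_by_severity")
  if (!is.null(contrasts))
    paths["contrasts"] <- write_table(contrasts, config$out_dir,
                                      "table_adjusted_contrasts")
  notes <- validation_notes(cohort)
  if (nrow(notes))
    paths["validation"] <- write_table(notes, config$out_dir,
                                       "validation_notes")

  manifest <- list(
    package_version = as.character(packageVersion("cdburden")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[setdiff(names(config), "generator")],
    generator = config$generator,
    unit_cost_label = uc$label,
    value_set = vs$name,
    n_respondents = nrow(sc))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", force = TRUE)
  paths["manifest"] <- manifest_path

  invisible(list(cohort = sc, costs = cb,
                 tables = list(characteristics = chr, eq5d = eqf,
                               components = components, by_severity = by_sev,
                               contrasts = contrasts, figures = figs),
                 stats = stats_tab, paths = paths))
}
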