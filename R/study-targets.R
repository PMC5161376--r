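## Adapter for the deposited patient-level study dataset and the computation
## of the published summary statistics from a mapped cohort.  The deposited
## spreadsheet's column layout is not documented anywhere, so the adapter is
## driven entirely by a user-written column mapping.

#' Read the deposited patient-level study dataset
#'
#' The study's patient-level responses were deposited as a supplementary
#' XLSX workbook whose column names and codings are not described in any
#' document; an analysis against it therefore requires a column mapping
#' written against the file itself (canonical name -> sheet column, see
#' [cohort_columns()]).  When the file is unavailable the function returns a
#' structured "unreachable" marker rather than failing, so pipelines can
#' report which published targets could not be recomputed and why.
#'
#' @param path path to the deposited workbook (or a CSV export of it).
#' @param mapping column mapping (named vector or YAML path); required for
#'   an XLSX/CSV with foreign headers.
#' @param sheet sheet index or name for XLSX input.
#' @return a validated canonical cohort, or an object of class
#'   `cd_unavailable` with a `reason` field when `path` is missing.
#' @export
read_s1_dataset <- function(path = NULL, mapping = NULL, sheet = 1) {
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    out <- list(reason = paste("patient-level study dataset not available",
                               "(file not found):",
                               if (is.null(path)) "<no path given>" else path))
    class(out) <- "cd_unavailable"
    return(out)
  }
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      out <- list(reason = "XLSX input requires the 'readxl' package")
      class(out) <- "cd_unavailable"
      return(out)
    }
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    write.csv(as.data.frame(readxl::read_excel(path, sheet = sheet)), tmp,
              row.names = FALSE)
    path <- tmp
  }
  read_cohort(path, mapping = mapping)
}

#' Published summary statistics recomputed from a cohort
#'
#' Recomputes, from a mapped patient-level cohort, the headline statistics
#' a full analysis reports: cohort mean utility index, mean monthly hours
#' missed from paid work among working respondents, mean early-departure
#' cost among pensioners, mean unpaid-work-loss cost, Spearman correlation
#' of utility with the P-HBI, agreement (kappa) between current activity and
#' the clinician's last assessment, and the mean total indirect cost.  Each
#' target is computed only if its inputs are present; otherwise it is
#' reported unreachable with the missing field named.
#'
#' @param cohort a canonical cohort (scored or not), or a `cd_unavailable`
#'   marker from [read_s1_dataset()].
#' @param unit_costs a `cd_unit_costs` table.
#' @param value_set,norms scoring inputs, see [score_cohort()].
#' @return `data.frame` with `target`, `value`, `n`, `status`, `note`.
#' @export
study_targets <- function(cohort, unit_costs = unit_cost_table(),
                          value_set = load_value_set("uk_mvh"),
                          norms = NULL) {
  targets <- c(mean_utility = "cohort mean EQ-5D utility index",
               mean_hours_missed = "mean monthly hours missed, working respondents",
               mean_early_departure_pension = "mean early-departure cost among pensioners",
               mean_unpaid_work_loss = "mean unpaid-work-loss cost",
               spearman_utility_phbi = "Spearman rho, utility vs P-HBI",
               kappa_activity = "Cohen's kappa, current vs clinician activity",
               mean_total_indirect = "mean total indirect cost")
  unreachable_all <- function(note) {
    data.frame(target = names(targets), value = NA_real_, n = NA_integer_,
               status = "unreachable", note = note, stringsAsFactors = FALSE)
  }
  if (inherits(cohort, "cd_unavailable")) return(unreachable_all(cohort$reason))

  sc <- score_cohort(cohort, value_set = value_set, norms = norms)
  cb <- cost_cohort(sc, unit_costs)
  out <- data.frame(target = character(0), value = numeric(0), n = integer(0),
                    status = character(0), note = character(0),
                    stringsAsFactors = FALSE)
  add <- function(target, value, n, status = "ok", note = "") {
    out <<- rbind(out, data.frame(target = target, value = value, n = n,
                                  status = status, note = note,
                                  stringsAsFactors = FALSE))
  }
  mean_of <- function(target, x, note_missing) {
    x <- x[!is.na(x)]
    if (length(x)) add(target, mean(x), length(x))
    else add(target, NA_real_, 0L, "unreachable", note_missing)
  }
  mean_of("mean_utility", sc$utility, "missing field: EQ-5D levels")
  hrs <- (cb$hours_absent + cb$hours_present)[sc$works %in% TRUE]
  mean_of("mean_hours_missed", hrs,
          "missing field: working time or absence answers")
  ed <- cb$early_departure[sc$on_pension %in% TRUE]
  mean_of("mean_early_departure_pension", ed,
          "missing field: pension / disability level")
  mean_of("mean_unpaid_work_loss", cb$unpaid_work_loss,
          "missing field: assistance hours")
  sp <- spearman_rho(sc$utility, sc$phbi_score)
  if (!is.na(sp$rho)) add("spearman_utility_phbi", sp$rho, sp$n)
  else add("spearman_utility_phbi", NA_real_, sp$n, "unreachable",
           "missing field: utility or P-HBI")
  clin <- ifelse(sc$clinician_severity == "unknown", NA,
                 ifelse(sc$clinician_severity == "moderate_or_severe",
                        "active", "remission"))
  ag <- agreement(as.character(sc$activity), clin)
  if (!is.na(ag$kappa)) add("kappa_activity", ag$kappa, ag$n)
  else add("kappa_activity", NA_real_, ag$n, "unreachable",
           "missing field: clinician assessment")
  mean_of("mean_total_indirect", cb$total_indirect,
          "missing field: one or more indirect components")
  out
}
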