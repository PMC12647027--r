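panel_col_types <- function() {
  readr::cols(
    institution_id = readr::col_character(),
    year = readr::col_integer(),
    beds = readr::col_double(),
    hhcw_kg = readr::col_double(),
    inpatient_days = readr::col_double(),
    discharges = readr::col_double(),
    cmi = readr::col_double(),
    icu_patients = readr::col_double(),
    inpatients = readr::col_double(),
    mdr_incidence = readr::col_double(),
    educational = readr::col_double(),
    .default = readr::col_guess()
  )
}

#' Read an institution-year panel from CSV
#'
#' Expects the documented panel schema (`institution_id, year, beds,
#' hhcw_kg, inpatient_days, discharges, cmi, icu_patients, inpatients,
#' mdr_incidence, educational`); unknown columns are preserved but ignored
#' downstream, and the `cmi` column may be absent when a DRG case table is
#' supplied separately. Malformed cells and invariant violations are
#' reported with their row number and field name.
#'
#' @param path CSV file path.
#' @return Tibble of validated institution-year records.
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) {
    stop("panel file not found: ", path, call. = FALSE)
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE))
  spec <- panel_col_types()
  spec$cols <- spec$cols[intersect(names(spec$cols), header)]
  # parsing problems are converted to row/field errors below, so the
  # generic vroom parse-issue warning is redundant noise
  panel <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE)
  )
  probs <- readr::problems(panel)
  if (nrow(probs) > 0) {
    first <- probs[1, ]
    # problems() reports file rows (header = row 1) and column indices
    field <- names(panel)[first$col]
    stop("malformed panel CSV: row ", first$row - 1, ", field ", field,
         " (expected ", first$expected, ", got ", first$actual, ")",
         call. = FALSE)
  }
  required <- c("institution_id", "year", "beds", "hhcw_kg",
                "inpatient_days", "discharges")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel CSV missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  checks <- list(
    beds = panel$beds > 0,
    hhcw_kg = panel$hhcw_kg >= 0,
    inpatient_days = panel$inpatient_days >= 0,
    discharges = panel$discharges >= 0
  )
  if ("mdr_incidence" %in% names(panel)) {
    checks$mdr_incidence <- panel$mdr_incidence >= 0
  }
  for (field in names(checks)) {
    ok <- checks[[field]] | is.na(checks[[field]])
    if (!all(ok)) {
      stop("invalid panel record: row ", which(!ok)[1], ", field ", field,
           " violates its constraint", call. = FALSE)
    }
  }
  panel
}

#' Read a DRG case table from CSV
#'
#' Schema: `institution_id, year, relative_weight, case_count`, one row per
#' DRG group per institution-year.
#'
#' @param path CSV file path.
#' @return Tibble of DRG case rows.
#' @export
read_drg_csv <- function(path) {
  if (!file.exists(path)) {
    stop("DRG file not found: ", path, call. = FALSE)
  }
  drg <- readr::read_csv(
    path,
    col_types = readr::cols(
      institution_id = readr::col_character(),
      year = readr::col_integer(),
      relative_weight = readr::col_double(),
      case_count = readr::col_double()
    ),
    progress = FALSE
  )
  required <- c("institution_id", "year", "relative_weight", "case_count")
  missing_cols <- setdiff(required, names(drg))
  if (length(missing_cols) > 0) {
    stop("DRG CSV missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_w <- which(drg$relative_weight <= 0)
  if (length(bad_w) > 0) {
    stop("invalid DRG record: row ", bad_w[1],
         ", field relative_weight must be > 0", call. = FALSE)
  }
  bad_c <- which(drg$case_count < 0)
  if (length(bad_c) > 0) {
    stop("invalid DRG record: row ", bad_c[1],
         ", field case_count must be >= 0", call. = FALSE)
  }
  drg
}

#' Write a validation report to disk
#'
#' Writes the full report as JSON plus one CSV per table analogue: the
#' group summary (size-quintile means/SDs), the correlation-comparison
#' table, the robust-regression table, and the paired fitted/residual
#' series of both indicator models.
#'
#' @param report A `cawi_report` from [run_validation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cawi_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(report$group_summary$groups,
                   file.path(dir, "group_summary.csv"))
  readr::write_csv(report$correlation_table,
                   file.path(dir, "correlation_comparison.csv"))
  readr::write_csv(report$regression_table,
                   file.path(dir, "regression_comparison.csv"))
  readr::write_csv(report$residuals,
                   file.path(dir, "residuals.csv"))
  invisible(dir)
}

test_result_to_list <- function(x) {
  list(test = x$test_name, statistic = x$statistic,
       df = x$df, p_value = x$p_value, tails = x$tails)
}

report_to_list <- function(report) {
  list(
    manifest = report$manifest,
    n_institutions = report$n_institutions,
    aggregation = report$aggregation,
    normality = lapply(report$normality, test_result_to_list),
    variance_f_test = test_result_to_list(report$variance_f_test),
    indicator_correlations = lapply(report$indicator_correlations, unclass),
    indicator_cross_correlation = unclass(report$indicator_cross_correlation),
    correlation_table = report$correlation_table,
    regression_table = report$regression_table,
    group_summary = list(
      groups = report$group_summary$groups,
      total_sd = as.list(report$group_summary$total_sd)
    ),
    residual_summary = report$residual_summary,
    dropped_records = report$dropped_records
  )
}
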