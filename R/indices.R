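#' Case-Mix Index from a DRG case table
#'
#' The CMI is the case-weighted mean DRG relative weight:
#' `sum(relative_weight * case_count) / sum(case_count)`. It proxies the
#' average clinical complexity and resource intensity of an institution's
#' patients.
#'
#' @param relative_weight Positive DRG relative weights, one per case group.
#' @param case_count Non-negative case counts, same length.
#' @return The dimensionless CMI, bounded by the min and max weight over
#'   groups with at least one case.
#' @export
#' @examples
#' compute_cmi(c(1.0, 2.0), c(50, 50))   # 1.5
compute_cmi <- function(relative_weight, case_count) {
  if (length(relative_weight) != length(case_count)) {
    stop("relative_weight and case_count must have equal length",
         call. = FALSE)
  }
  if (any(relative_weight <= 0)) {
    stop("DRG relative weights must be > 0", call. = FALSE)
  }
  if (any(case_count < 0)) {
    stop("case counts must be >= 0", call. = FALSE)
  }
  total <- sum(case_count)
  if (total <= 0) {
    stop("undefined CMI: total case count is zero", call. = FALSE)
  }
  sum(relative_weight * case_count) / total
}

#' Average length of stay
#'
#' LOS is total inpatient days divided by total discharges, i.e. the average
#' number of inpatient days per hospital stay.
#'
#' @param inpatient_days Total inpatient days (>= 0).
#' @param discharges Total discharges (> 0). Vectorized.
#' @return LOS in days.
#' @export
#' @examples
#' compute_los(1000, 100)   # 10
compute_los <- function(inpatient_days, discharges) {
  if (any(inpatient_days < 0)) {
    stop("inpatient_days must be >= 0", call. = FALSE)
  }
  if (any(discharges <= 0)) {
    stop("undefined LOS: discharges must be > 0", call. = FALSE)
  }
  inpatient_days / discharges
}

#' Hazardous-waste generation rate in kg/bed/day
#'
#' The conventional benchmarking rate: annual hazardous-waste mass divided by
#' bed count times the calendar days of that year (366 in leap years unless
#' `leap_years = FALSE`).
#'
#' @param hhcw_kg Annual hazardous healthcare waste mass in kg (>= 0).
#' @param beds Bed count (> 0).
#' @param year Calendar year, used for the day denominator.
#' @param leap_years Use 366-day denominators in leap years (default `TRUE`).
#' @return Generation rate in kg/bed/day. Vectorized.
#' @export
#' @examples
#' compute_generation_rate(3650, 10, 2017)   # 1.0
compute_generation_rate <- function(hhcw_kg, beds, year, leap_years = TRUE) {
  if (any(beds <= 0)) {
    stop("beds must be > 0", call. = FALSE)
  }
  if (any(hhcw_kg < 0)) {
    stop("hhcw_kg must be >= 0", call. = FALSE)
  }
  hhcw_kg / (beds * days_in_year(year, leap_years = leap_years))
}

#' Complexity-Adjusted Waste Index
#'
#' `CAWI = GR * CMI / LOS`: the raw kg/bed/day rate multiplied by the
#' Case-Mix Index (rewarding clinical complexity) and divided by the average
#' length of stay (adjusting for care intensity, since shorter stays mean
#' more intensive treatment and higher daily waste). Nominal unit
#' kg/bed/day^2; in practice a comparative, scale-independent metric.
#'
#' @param gr Generation rate in kg/bed/day (>= 0).
#' @param cmi Case-Mix Index (> 0).
#' @param los Average length of stay in days (> 0).
#' @return CAWI. Vectorized; linear in `gr`, increasing in `cmi`, decreasing
#'   in `los`.
#' @export
#' @examples
#' compute_cawi(0.5, 1.2, 6)   # 0.1
compute_cawi <- function(gr, cmi, los) {
  if (any(los <= 0)) {
    stop("undefined CAWI: los must be > 0", call. = FALSE)
  }
  if (any(cmi <= 0)) {
    stop("undefined CAWI: cmi must be > 0", call. = FALSE)
  }
  if (any(gr < 0)) {
    stop("gr must be >= 0", call. = FALSE)
  }
  gr * cmi / los
}

#' Derive per-institution index records from an institution-year panel
#'
#' Computes the generation rate, CMI, LOS and CAWI for each record, then
#' aggregates. Under `"institution_mean"` (default) the yearly GR, CMI and
#' LOS are averaged per institution first and CAWI is computed from the
#' averaged components; control variables are averaged across years. Under
#' `"pooled"` every institution-year becomes its own index record.
#'
#' Records with undefined LOS (zero discharges) or no usable CMI are dropped
#' with a warning stating how many. When a DRG case table is supplied it
#' takes precedence over a precomputed `cmi` column; a discrepancy above
#' 1e-6 between the two is reported via a warning.
#'
#' @param panel Tibble/data.frame of institution-year records with columns
#'   `institution_id, year, beds, hhcw_kg, inpatient_days, discharges` and
#'   at least one of `cmi` or a `drg` table; optional control columns
#'   `icu_patients, inpatients, mdr_incidence, educational` are carried
#'   through.
#' @param drg Optional DRG case table with columns
#'   `institution_id, year, relative_weight, case_count`.
#' @param aggregation `"institution_mean"` (default) or `"pooled"`.
#' @param leap_years Passed to [compute_generation_rate()].
#' @return Tibble of index records: `institution_id` (and `year` when
#'   pooled), `beds`, `gr`, `cmi`, `los`, `cawi`, plus carried-through
#'   control variables.
#' @export
compute_index_records <- function(panel,
                                  drg = NULL,
                                  aggregation = c("institution_mean", "pooled"),
                                  leap_years = TRUE) {
  aggregation <- match.arg(aggregation)
  if (nrow(panel) == 0) {
    stop("empty panel: no records to index", call. = FALSE)
  }
  required <- c("institution_id", "year", "beds", "hhcw_kg",
                "inpatient_days", "discharges")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel <- tibble::as_tibble(panel)

  if (!is.null(drg)) {
    drg_cmi <- drg |>
      dplyr::group_by(.data$institution_id, .data$year) |>
      dplyr::summarise(
        cmi_drg = compute_cmi(.data$relative_weight, .data$case_count),
        .groups = "drop"
      )
    panel <- dplyr::left_join(panel, drg_cmi,
                              by = c("institution_id", "year"))
    if ("cmi" %in% names(panel)) {
      both <- !is.na(panel$cmi) & !is.na(panel$cmi_drg)
      disc <- both & abs(panel$cmi - panel$cmi_drg) > 1e-6
      if (any(disc)) {
        warning(sum(disc), " record(s) where the DRG-derived CMI differs ",
                "from the precomputed value by more than 1e-6; ",
                "the DRG case table takes precedence", call. = FALSE)
      }
      panel$cmi <- ifelse(is.na(panel$cmi_drg), panel$cmi, panel$cmi_drg)
    } else {
      panel$cmi <- panel$cmi_drg
    }
    panel$cmi_drg <- NULL
  }
  if (!("cmi" %in% names(panel))) {
    stop("no CMI available: supply a `cmi` column or a DRG case table",
         call. = FALSE)
  }

  bad <- panel$discharges <= 0 | is.na(panel$cmi) | panel$cmi <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " record(s) with undefined LOS or CMI",
            call. = FALSE)
    panel <- panel[!bad, , drop = FALSE]
  }
  if (nrow(panel) == 0) {
    stop("no valid records remain after dropping undefined LOS/CMI",
         call. = FALSE)
  }

  controls <- intersect(
    c("icu_patients", "inpatients", "mdr_incidence", "educational"),
    names(panel)
  )

  yearly <- panel |>
    dplyr::mutate(
      gr = compute_generation_rate(.data$hhcw_kg, .data$beds, .data$year,
                                   leap_years = leap_years),
      los = compute_los(.data$inpatient_days, .data$discharges)
    )

  if (aggregation == "pooled") {
    out <- yearly |>
      dplyr::mutate(cawi = compute_cawi(.data$gr, .data$cmi, .data$los)) |>
      dplyr::select(dplyr::all_of(c("institution_id", "year", "beds",
                                    "gr", "cmi", "los", "cawi", controls)))
  } else {
    out <- yearly |>
      dplyr::group_by(.data$institution_id) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(c("beds", "gr", "cmi", "los", controls)),
                      mean),
        .groups = "drop"
      ) |>
      dplyr::mutate(cawi = compute_cawi(.data$gr, .data$cmi, .data$los)) |>
      dplyr::select(dplyr::all_of(c("institution_id", "beds", "gr", "cmi",
                                    "los", "cawi", controls)))
  }
  out
}
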