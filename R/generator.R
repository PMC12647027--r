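#' Default parameters for the synthetic hospital-panel generator
#'
#' Returns the study conditions the generator emulates: 94 inpatient
#' institutions observed over 2017-2021, bed capacities spanning 30-3513,
#' patient complexity (CMI) increasing and length of stay (LOS) decreasing
#' with hospital size, and daily hazardous-waste intensity increasing in CMI
#' and decreasing in LOS.
#'
#' Parameter values are anchored to the magnitudes national benchmarking data
#' exhibit: the CMI gradient runs from about 0.76 in the smallest size
#' quintile to about 1.29 in the largest, LOS from about 17.2 down to about
#' 6.9 days, and the raw generation rate from about 0.26 to 0.51 kg/bed/day.
#'
#' @param n_institutions Number of institutions (>= 5 so quintiles are
#'   non-degenerate).
#' @param years Calendar years of the panel.
#' @param seed Integer seed; equal seeds give bit-identical panels.
#' @return A `cawi_generator_params` list. Fields:
#' \describe{
#'   \item{bed_log_mean, bed_log_sd, bed_min, bed_max}{log-normal bed-count
#'     distribution with clip bounds (beds).}
#'   \item{cmi_intercept, cmi_slope, cmi_noise_sd}{CMI model
#'     `CMI = a0 + a1 log(beds) + N(0, sd)`, clipped to > 0.1.}
#'   \item{los_intercept, los_slope, los_noise_sd}{log-LOS model
#'     `LOS = exp(b0 - b1 log(beds) + N(0, sd))` (days).}
#'   \item{gr_intercept, gr_cmi_effect, gr_los_effect, gr_noise_sd}{latent
#'     log generation-rate model
#'     `log GR = c0 + c1 log(CMI) - c2 log(LOS) + N(0, sd)` (kg/bed/day).}
#'   \item{occupancy}{fixed bed-occupancy scalar linking beds to inpatient
#'     days.}
#'   \item{icu_share_base, icu_share_slope}{logit-scale ICU share of
#'     inpatients as a function of log(beds).}
#'   \item{mdr_base, mdr_icu_effect, mdr_noise_sd}{MDR-HAI incidence (cases
#'     per 100,000 inpatient days), log-linear in log(1 + ICU patients).}
#'   \item{edu_logit_intercept, edu_logit_slope}{logistic educational-flag
#'     model in log(beds); the largest institutions are usually academic.}
#' }
#' @export
#' @examples
#' p <- default_params(seed = 1)
#' p$n_institutions
default_params <- function(n_institutions = 94L,
                           years = 2017:2021,
                           seed = 1L) {
  params <- structure(list(
    n_institutions = as.integer(n_institutions),
    years = as.integer(years),
    bed_log_mean = 6.1,
    bed_log_sd = 0.8,
    bed_min = 30,
    bed_max = 3513,
    cmi_intercept = -0.21,
    cmi_slope = 0.20,
    cmi_noise_sd = 0.5,
    los_intercept = 4.55,
    los_slope = 0.35,
    los_noise_sd = 0.5,
    gr_intercept = 0.07,
    gr_cmi_effect = 0.5,
    gr_los_effect = 0.45,
    gr_noise_sd = 0.35,
    occupancy = 0.8,
    icu_share_base = -5.9,
    icu_share_slope = 0.43,
    mdr_base = 2,
    mdr_icu_effect = 0.35,
    mdr_noise_sd = 0.3,
    edu_logit_intercept = -10.8,
    edu_logit_slope = 1.7,
    seed = as.integer(seed)
  ), class = "cawi_generator_params")
  validate_params(params)
  params
}

validate_params <- function(params) {
  stopifnot(inherits(params, "cawi_generator_params") || is.list(params))
  if (params$n_institutions < 5) {
    stop("invalid generator params: n_institutions must be >= 5 ",
         "(quintile groups would be degenerate)", call. = FALSE)
  }
  if (length(params$years) < 1) {
    stop("invalid generator params: at least one year required", call. = FALSE)
  }
  if (params$bed_min <= 0 || params$bed_max < params$bed_min) {
    stop("invalid generator params: bed clip bounds must satisfy ",
         "0 < bed_min <= bed_max", call. = FALSE)
  }
  for (f in c("cmi_noise_sd", "los_noise_sd", "gr_noise_sd", "mdr_noise_sd")) {
    if (params[[f]] < 0) {
      stop("invalid generator params: ", f, " must be >= 0", call. = FALSE)
    }
  }
  if (params$occupancy <= 0 || params$occupancy > 1) {
    stop("invalid generator params: occupancy must be in (0, 1]",
         call. = FALSE)
  }
  invisible(params)
}

#' Number of calendar days in a year
#'
#' @param year Integer calendar year(s).
#' @param leap_years If `FALSE`, always return 365 (fixed-denominator
#'   convention); if `TRUE` (default), return 366 for leap years.
#' @return Integer vector of day counts.
#' @export
days_in_year <- function(year, leap_years = TRUE) {
  if (!leap_years) {
    return(rep(365L, length(year)))
  }
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  ifelse(leap, 366L, 365L)
}

#' Generate a synthetic hospital-year panel with known ground truth
#'
#' Simulates an institution-year panel with the dependence structure national
#' hazardous-waste benchmarking data exhibit. Bed counts are drawn once per
#' institution (log-normal, clipped) and held fixed across years; per
#' institution, CMI rises and LOS falls with log bed count, and the latent
#' log generation rate rises in log(CMI) and falls in log(LOS). Annual waste
#' mass is the latent rate times beds times calendar days, so the realized
#' kg/bed/day rate reproduces the latent rate exactly. ICU patients are a
#' binomial share of inpatients (share increasing with size), MDR incidence
#' is log-linear in ICU load, and the educational flag is a logistic draw in
#' log(beds).
#'
#' @param params A `cawi_generator_params` list, e.g. from [default_params()].
#' @return A list with components:
#' \describe{
#'   \item{panel}{tibble of institution-year records with columns
#'     `institution_id, year, beds, hhcw_kg, inpatient_days, discharges,
#'     cmi, icu_patients, inpatients, mdr_incidence, educational`.}
#'   \item{truth}{ground-truth list: the realized effect sizes
#'     (`gr_cmi_effect`, `gr_los_effect`) and per-institution latent
#'     `gr`, `cmi`, `los`, `beds`.}
#' }
#' @export
#' @examples
#' sim <- generate_panel(default_params(seed = 42))
#' nrow(sim$panel)   # 94 institutions x 5 years
generate_panel <- function(params = default_params()) {
  validate_params(params)
  set.seed(params$seed)

  n <- params$n_institutions
  log_beds_raw <- rnorm(n, params$bed_log_mean, params$bed_log_sd)
  beds <- round(pmin(pmax(exp(log_beds_raw), params$bed_min), params$bed_max))
  lb <- log(beds)

  cmi <- params$cmi_intercept + params$cmi_slope * lb +
    rnorm(n, 0, params$cmi_noise_sd)
  cmi <- pmax(cmi, 0.1)

  los <- exp(params$los_intercept - params$los_slope * lb +
               rnorm(n, 0, params$los_noise_sd))

  log_gr <- params$gr_intercept +
    params$gr_cmi_effect * log(cmi) -
    params$gr_los_effect * log(los) +
    rnorm(n, 0, params$gr_noise_sd)
  gr <- exp(log_gr)

  icu_share <- stats::plogis(params$icu_share_base +
                               params$icu_share_slope * lb)
  educational <- as.integer(
    runif(n) < stats::plogis(params$edu_logit_intercept +
                               params$edu_logit_slope * lb)
  )

  ids <- sprintf("H%03d", seq_len(n))
  years <- params$years
  rows <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    dy <- days_in_year(yr)
    inpatient_days <- beds * dy * params$occupancy
    discharges <- pmax(round(inpatient_days / los), 1)
    inpatients <- discharges
    icu_patients <- rbinom(n, size = inpatients, prob = icu_share)
    mdr <- params$mdr_base *
      exp(params$mdr_icu_effect * log1p(icu_patients) +
            rnorm(n, 0, params$mdr_noise_sd))
    rows[[k]] <- tibble::tibble(
      institution_id = ids,
      year = rep(yr, n),
      beds = beds,
      hhcw_kg = gr * beds * dy,
      inpatient_days = inpatient_days,
      discharges = discharges,
      cmi = cmi,
      icu_patients = icu_patients,
      inpatients = inpatients,
      mdr_incidence = mdr,
      educational = educational
    )
  }
  panel <- dplyr::arrange(dplyr::bind_rows(rows),
                          .data$institution_id, .data$year)

  truth <- list(
    gr_cmi_effect = params$gr_cmi_effect,
    gr_los_effect = params$gr_los_effect,
    institutions = tibble::tibble(
      institution_id = ids, beds = beds, cmi = cmi, los = los, latent_gr = gr
    )
  )
  list(panel = panel, truth = truth)
}

#' Write a panel as CSV with a ground-truth JSON sidecar
#'
#' @param sim A list from [generate_panel()] (or a bare panel tibble, in
#'   which case no sidecar is written).
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(sim, path) {
  panel <- if (is.data.frame(sim)) sim else sim$panel
  readr::write_csv(panel, path)
  if (!is.data.frame(sim) && !is.null(sim$truth)) {
    truth <- sim$truth
    truth$institutions <- as.data.frame(truth$institutions)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
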