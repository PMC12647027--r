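#' Configuration for the validation pipeline
#'
#' Bundles every tunable of [run_validation()]: the input source (synthetic
#' generator parameters or a panel CSV path), the aggregation convention,
#' the control variables to benchmark against, how correlation coefficients
#' are compared, and the robust-regression options.
#'
#' @param input A `cawi_generator_params` list (synthetic input) or a panel
#'   CSV path. Defaults to [default_params()] with `seed`.
#' @param drg Optional DRG case-table CSV path or tibble.
#' @param aggregation `"institution_mean"` (default) or `"pooled"`.
#' @param control_vars Control variables, a subset of
#'   `c("icu_patients", "mdr_incidence", "inpatients", "educational")`.
#' @param comparison `"fisher"`, `"steiger"`, or `"both"` (default): how the
#'   per-control correlations of the two indicators are compared.
#' @param psi,tuning_c,tol,max_iter Robust-regression options, see
#'   [huber_regression()].
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the synthetic input.
#' @param leap_years Use calendar day counts (366 in leap years) in the
#'   generation-rate denominator.
#' @return A `cawi_run_config` list.
#' @export
run_config <- function(input = NULL,
                       drg = NULL,
                       aggregation = c("institution_mean", "pooled"),
                       control_vars = c("icu_patients", "mdr_incidence",
                                        "inpatients", "educational"),
                       comparison = c("both", "fisher", "steiger"),
                       psi = "huber",
                       tuning_c = 1.345,
                       tol = 1e-8,
                       max_iter = 50L,
                       alpha = 0.05,
                       seed = 1L,
                       leap_years = TRUE) {
  aggregation <- match.arg(aggregation)
  comparison <- match.arg(comparison)
  allowed <- c("icu_patients", "mdr_incidence", "inpatients", "educational")
  bad <- setdiff(control_vars, allowed)
  if (length(bad) > 0) {
    stop("unknown control variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (is.null(input)) {
    input <- default_params(seed = seed)
  }
  structure(
    list(input = input, drg = drg, aggregation = aggregation,
         control_vars = control_vars, comparison = comparison,
         psi = psi, tuning_c = tuning_c, tol = tol,
         max_iter = as.integer(max_iter), alpha = alpha,
         seed = as.integer(seed), leap_years = leap_years),
    class = "cawi_run_config"
  )
}

resolve_input <- function(config) {
  input <- config$input
  if (inherits(input, "cawi_generator_params")) {
    input$seed <- config$seed
    generate_panel(input)$panel
  } else if (is.character(input)) {
    read_panel_csv(input)
  } else if (is.data.frame(input)) {
    tibble::as_tibble(input)
  } else {
    stop("unresolvable input: supply generator params, a data frame, or a ",
         "CSV path", call. = FALSE)
  }
}

#' Run the full indicator-validation pipeline
#'
#' Executes, in order: indicator computation and aggregation, quintile
#' stratification with group summaries, Shapiro-Wilk normality screening of
#' each indicator, the variance F-test of GR versus CAWI dispersion,
#' Spearman correlations of CMI and LOS against GR, Spearman correlations
#' of both waste indicators against each numeric control variable with a
#' Fisher z and/or Steiger comparison per control, univariate robust
#' regressions of each indicator on each control variable, and residual
#' diagnostics for both indicator models. Deterministic given the config
#' (and its seed, for synthetic input).
#'
#' @param config A `cawi_run_config` from [run_config()].
#' @return A `cawi_report` list; see [write_report()] for serialization.
#' @export
#' @examples
#' rep <- run_validation(run_config(seed = 7))
#' rep$variance_f_test
run_validation <- function(config = run_config()) {
  stopifnot(inherits(config, "cawi_run_config"))

  panel <- resolve_input(config)
  drg <- config$drg
  if (is.character(drg)) {
    drg <- read_drg_csv(drg)
  }

  dropped <- 0L
  records <- withCallingHandlers(
    compute_index_records(panel, drg = drg,
                          aggregation = config$aggregation,
                          leap_years = config$leap_years),
    warning = function(w) {
      m <- regmatches(conditionMessage(w),
                      regexpr("^dropping [0-9]+", conditionMessage(w)))
      if (length(m) == 1) {
        dropped <<- as.integer(sub("dropping ", "", m))
      }
    }
  )
  n_inst <- length(unique(records$institution_id))
  if (n_inst < 5) {
    stop("degenerate panel at stratification stage: fewer than 5 ",
         "institutions after aggregation", call. = FALSE)
  }

  grouping <- assign_quintile_groups(
    dplyr::distinct(records, .data$institution_id,
                    .keep_all = TRUE)[, c("institution_id", "beds")]
  )
  group_summary <- summarize_groups(records, grouping)

  indicators <- c("gr", "cmi", "los", "cawi")
  normality <- lapply(setNames(indicators, indicators), function(v) {
    shapiro_wilk(records[[v]])
  })

  f_test <- variance_f_test(records$gr, records$cawi)

  indicator_correlations <- list(
    cmi_vs_gr = spearman_correlation(records$cmi, records$gr),
    los_vs_gr = spearman_correlation(records$los, records$gr)
  )
  cross <- spearman_correlation(records$gr, records$cawi)

  numeric_controls <- intersect(
    config$control_vars, c("icu_patients", "mdr_incidence", "inpatients")
  )
  corr_rows <- lapply(numeric_controls, function(ctrl) {
    r_gr <- spearman_correlation(records[[ctrl]], records$gr)
    r_cawi <- spearman_correlation(records[[ctrl]], records$cawi)
    row <- tibble::tibble(
      control = ctrl, n = r_gr$n,
      rho_gr = r_gr$rho, p_gr = r_gr$p_value,
      rho_cawi = r_cawi$rho, p_cawi = r_cawi$p_value
    )
    if (config$comparison %in% c("fisher", "both")) {
      ft <- fisher_z_compare(r_cawi$rho, r_cawi$n, r_gr$rho, r_gr$n)
      row$fisher_z <- ft$statistic
      row$fisher_p <- ft$p_value
    }
    if (config$comparison %in% c("steiger", "both")) {
      st <- steiger_compare_dependent(r_cawi$rho, r_gr$rho, cross$rho,
                                      r_gr$n)
      row$steiger_z <- st$statistic
      row$steiger_p <- st$p_value
    }
    row
  })
  correlation_table <- dplyr::bind_rows(corr_rows)

  reg_rows <- list()
  residual_rows <- list()
  residual_summary <- list()
  for (ind in c("gr", "cawi")) {
    for (ctrl in config$control_vars) {
      xv <- records[[ctrl]]
      if (sd(xv) == 0) {
        warning("control variable ", ctrl, " is constant; regression on it ",
                "skipped", call. = FALSE)
        next
      }
      fit <- huber_regression(xv, records[[ind]],
                              tuning_c = config$tuning_c,
                              max_iter = config$max_iter,
                              tol = config$tol,
                              psi = config$psi)
      diag <- residual_diagnostics(fit)
      key <- paste(ind, ctrl, sep = "~")
      reg_rows[[key]] <- tibble::tibble(
        indicator = ind, control = ctrl,
        coefficient = unname(fit$coefficients[2]),
        se = unname(fit$se[2]),
        p_value = unname(fit$p_value[2]),
        scale = fit$scale,
        iterations = fit$iterations,
        converged = fit$converged
      )
      residual_rows[[key]] <- dplyr::mutate(diag$series,
                                            indicator = ind, control = ctrl)
      residual_summary[[key]] <- list(residual_sd = diag$residual_sd,
                                      spread_slope = diag$spread_slope)
    }
  }
  regression_table <- dplyr::bind_rows(reg_rows)
  residuals <- dplyr::bind_rows(residual_rows)[
    , c("indicator", "control", "fitted", "residual")]

  structure(
    list(
      manifest = list(
        package_version = as.character(packageVersion("cawi")),
        seed = config$seed,
        aggregation = config$aggregation,
        comparison = config$comparison,
        psi = config$psi,
        tuning_c = config$tuning_c,
        alpha = config$alpha,
        leap_years = config$leap_years,
        control_vars = config$control_vars,
        input = if (is.character(config$input)) config$input else "synthetic"
      ),
      n_institutions = n_inst,
      aggregation = config$aggregation,
      records = records,
      grouping = grouping,
      group_summary = group_summary,
      normality = normality,
      variance_f_test = f_test,
      indicator_correlations = indicator_correlations,
      indicator_cross_correlation = cross,
      correlation_table = correlation_table,
      regression_table = regression_table,
      residuals = residuals,
      residual_summary = residual_summary,
      dropped_records = dropped
    ),
    class = "cawi_report"
  )
}

#' @export
print.cawi_report <- function(x, ...) {
  cat("CAWI validation report —", x$n_institutions, "institutions,",
      x$aggregation, "aggregation\n")
  cat(sprintf("Dispersion: SD(GR) = %.4f vs SD(CAWI) = %.4f (F = %.2f, p = %.3g)\n",
              x$group_summary$total_sd[["gr"]],
              x$group_summary$total_sd[["cawi"]],
              x$variance_f_test$statistic, x$variance_f_test$p_value))
  cat(sprintf("Spearman CMI~GR: %.3f; LOS~GR: %.3f\n",
              x$indicator_correlations$cmi_vs_gr$rho,
              x$indicator_correlations$los_vs_gr$rho))
  cat("\nCorrelation comparison (controls):\n")
  print(x$correlation_table, ...)
  cat("\nRobust regressions:\n")
  print(x$regression_table, ...)
  invisible(x)
}
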