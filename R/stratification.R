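#' Assign institutions to bed-capacity quintile groups
#'
#' Institutions are sorted by bed count (ties broken by `institution_id`,
#' stable) and split into five contiguous blocks whose sizes differ by at
#' most one, so each group holds approximately 20% of the institutions.
#' Remainder institutions are allocated to the lowest-index (smallest-bed)
#' groups: 94 institutions yield sizes 19, 19, 19, 19, 18.
#'
#' @param records Tibble of index records with `institution_id` and `beds`
#'   (one row per institution).
#' @param n_groups Number of groups (default 5, i.e. quintiles).
#' @return Tibble `institution_id`, `group` (integer 1..n_groups, 1 =
#'   smallest institutions).
#' @export
assign_quintile_groups <- function(records, n_groups = 5L) {
  n <- nrow(records)
  if (n < n_groups) {
    stop("need at least ", n_groups, " institutions for ", n_groups,
         "-group stratification, got ", n, call. = FALSE)
  }
  if (anyDuplicated(records$institution_id)) {
    stop("records must contain one row per institution", call. = FALSE)
  }
  ord <- order(records$beds, records$institution_id)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  tibble::tibble(
    institution_id = records$institution_id[ord],
    group = rep(seq_len(n_groups), times = sizes)
  )
}

#' Group summaries of the waste indicators
#'
#' Per-group arithmetic means and sample (n-1) standard deviations of the
#' generation rate, CMI, LOS and CAWI, with the observed bed range and group
#' size, plus the overall sample SDs of GR and CAWI across all institutions
#' (the headline dispersion comparison between the raw rate and the adjusted
#' index).
#'
#' @param records Tibble of index records (one row per institution) with
#'   columns `institution_id, beds, gr, cmi, los, cawi`.
#' @param grouping Tibble from [assign_quintile_groups()]; computed from
#'   `records` when `NULL`.
#' @return A list of class `cawi_group_summary`:
#' \describe{
#'   \item{groups}{tibble with `group, bed_min, bed_max, n` and
#'     `<indicator>_mean` / `<indicator>_sd` for gr, cmi, los, cawi.}
#'   \item{total_sd}{named numeric: overall sample SD of `gr` and `cawi`.}
#' }
#' @export
summarize_groups <- function(records, grouping = NULL) {
  if (is.null(grouping)) {
    grouping <- assign_quintile_groups(records)
  }
  if (!all(records$institution_id %in% grouping$institution_id)) {
    stop("grouping does not cover all institutions", call. = FALSE)
  }
  indicators <- c("gr", "cmi", "los", "cawi")
  joined <- dplyr::inner_join(records, grouping, by = "institution_id")
  groups <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      bed_min = min(.data$beds),
      bed_max = max(.data$beds),
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(indicators),
                    list(mean = mean, sd = sd)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)
  structure(
    list(
      groups = groups,
      total_sd = c(gr = sd(records$gr), cawi = sd(records$cawi))
    ),
    class = "cawi_group_summary"
  )
}

#' @export
print.cawi_group_summary <- function(x, ...) {
  cat("Hospital size-quintile summary (", nrow(x$groups), " groups)\n",
      sep = "")
  print(x$groups, ...)
  cat(sprintf("Overall sample SD: GR %.4f, CAWI %.4f\n",
              x$total_sd[["gr"]], x$total_sd[["cawi"]]))
  invisible(x)
}
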