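#' Residual scatter of the two indicator models
#'
#' Fitted-versus-residual panels for the GR and CAWI robust regressions,
#' faceted by control variable — the usual visual check that the adjusted
#' index leaves a tighter, more homoscedastic residual cloud than the raw
#' rate. Requires ggplot2.
#'
#' @param report A `cawi_report` from [run_validation()].
#' @param free_scales Let each indicator facet scale its own axes (the two
#'   indicators live on very different scales); default `TRUE`.
#' @return A ggplot object.
#' @export
plot_residuals <- function(report, free_scales = TRUE) {
  stopifnot(inherits(report, "cawi_report"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_residuals() requires the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(report$residuals,
                  ggplot2::aes(x = .data$fitted, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_grid(
      indicator ~ control,
      scales = if (free_scales) "free" else "fixed"
    ) +
    ggplot2::labs(x = "Fitted value", y = "Residual",
                  title = "Robust-regression residuals: GR vs CAWI models") +
    ggplot2::theme_bw()
}
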