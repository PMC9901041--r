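#' Metabolizable energy by diet arm
#'
#' Box-and-point plot of per-participant host metabolizable energy for each
#' diet, mirroring the headline comparison of a crossover feeding study.
#'
#' @param analysis output of [analyze_cohort()] (or any data frame with
#'   `diet` and `me_pct` columns).
#' @return a ggplot object.
#' @export
plot_me_by_diet <- function(analysis) {
  ggplot2::ggplot(analysis, ggplot2::aes(x = .data$diet, y = .data$me_pct,
                                         colour = .data$diet)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4,
                          show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "host metabolizable energy (%)") +
    ggplot2::theme_minimal()
}

#' Model response across colonic transit times
#'
#' Line plot of a [sensitivity_ctt()] table: metabolizable energy and
#' absorbed SCFA as functions of the colonic residence time.
#'
#' @param sens output of [sensitivity_ctt()].
#' @return a ggplot object.
#' @export
plot_ctt_sensitivity <- function(sens) {
  long <- tidyr::pivot_longer(
    sens[, c("ctt_h", "me_pct", "scfa_absorbed_total")],
    -"ctt_h", names_to = "quantity", values_to = "value"
  )
  labels <- c(me_pct = "metabolizable energy (%)",
              scfa_absorbed_total = "SCFA absorbed (gCOD/day)")
  long$quantity <- labels[long$quantity]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ctt_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "colonic transit time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname build_report
#' @param object a `gutcod_report` object.
#' @method autoplot gutcod_report
#' @export
autoplot.gutcod_report <- function(object, ...) {
  plot_me_by_diet(object$analysis)
}
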