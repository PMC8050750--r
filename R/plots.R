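#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of a feature table's values
#'
#' @param object A `fhir_feature_table`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot: value histogram, facetted by gender when present.
#' @method autoplot fhir_feature_table
#' @export
autoplot.fhir_feature_table <- function(object, bins = 40, ...) {
  tbl <- tibble::as_tibble(object)
  unit <- if ("unit" %in% names(tbl)) {
    u <- unique(stats::na.omit(tbl$unit))
    if (length(u) == 1) u else NULL
  }
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(
      x = if (!is.null(unit)) paste0("value (", unit, ")") else "value",
      y = "observations"
    ) +
    ggplot2::theme_minimal()
  if ("gender" %in% names(tbl)) {
    p <- p + ggplot2::facet_wrap(~gender)
  }
  p
}

#' @rdname autoplot.fhir_feature_table
#' @param t A `fhir_feature_table`.
#' @export
plot_feature_distribution <- function(t, bins = 40) {
  autoplot.fhir_feature_table(t, bins = bins)
}

#' Bar chart of a scenario report's groups
#'
#' Proportion-style reports (anemia) show `pct_anemic` per group;
#' mean-style reports (drug scenario) show `mean_value`.
#'
#' @param object A `fhir_scenario_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fhir_scenario_report
#' @export
autoplot.fhir_scenario_report <- function(object, ...) {
  g <- object$groups
  if ("pct_anemic" %in% names(g)) {
    g$group <- paste(g$gender, ifelse(g$cancer, "cancer", "no cancer"))
    ggplot2::ggplot(g, ggplot2::aes(
      x = .data$group, y = .data$pct_anemic,
      fill = .data$cancer
    )) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "% anemic", title = object$scenario) +
      ggplot2::guides(fill = "none") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(g, ggplot2::aes(
      x = .data$group, y = .data$mean_value,
      fill = .data$group
    )) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "group mean", title = object$scenario) +
      ggplot2::guides(fill = "none") +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.fhir_scenario_report
#' @param report A `fhir_scenario_report`.
#' @export
plot_scenario_groups <- function(report) {
  autoplot.fhir_scenario_report(report)
}
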