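#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scenario report
#'
#' @param x A `fhir_scenario_report`.
#' @param ... Unused.
#' @return The per-group tibble of the report.
#' @method tidy fhir_scenario_report
#' @export
tidy.fhir_scenario_report <- function(x, ...) {
  x$groups
}

#' One-row summary of a scenario report
#'
#' @param x A `fhir_scenario_report`.
#' @param ... Unused.
#' @return A one-row tibble: scenario name, number of groups, total n, and
#'   the smallest test p-value.
#' @method glance fhir_scenario_report
#' @export
glance.fhir_scenario_report <- function(x, ...) {
  n_col <- intersect(c("n_patients", "n_results"), names(x$groups))[1]
  tibble::tibble(
    scenario = x$scenario,
    n_groups = nrow(x$groups),
    n_total = sum(x$groups[[n_col]]),
    p_value = if (!is.null(x$tests) && any(!is.na(x$tests$p_value))) {
      min(x$tests$p_value, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' Tidy a filter result
#'
#' @param x A `fhir_filter_result`.
#' @param ... Unused.
#' @return The per-criterion audit tibble (criterion index, polarity,
#'   grounding resource type, mode, base resources removed).
#' @method tidy fhir_filter_result
#' @export
tidy.fhir_filter_result <- function(x, ...) {
  x$audit
}

#' One-row summary of a filter result
#'
#' @param x A `fhir_filter_result`.
#' @param ... Unused.
#' @return A one-row tibble with base-set size, kept count, removed count
#'   and number of distinct patients kept.
#' @method glance fhir_filter_result
#' @export
glance.fhir_filter_result <- function(x, ...) {
  tibble::tibble(
    n_base = x$n_base,
    n_kept = nrow(x$kept),
    n_removed = x$n_base - nrow(x$kept),
    n_patients = length(unique(x$kept$subject_ref))
  )
}
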