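#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a margin sequence into per-state descriptors
#'
#' @param x A [margin_sequence()].
#' @param ... Unused.
#' @return A tibble with one row per saved margin: `time_years`,
#'   `area_mm2`, `perimeter_mm`, `circularity`, `focality`,
#'   `gini_focality`.
#' @method tidy margin_sequence
#' @export
tidy.margin_sequence <- function(x, ...) {
  purrr::map(x$states, function(st) {
    dplyr::mutate(shape_descriptors(st), time_years = st$time_years,
                  .before = 1)
  }) |> purrr::list_rbind()
}

#' Tidy a ground-truth rate into its per-step margin averages
#'
#' @param x A `ground_truth_rate` from [ground_truth_lambda()].
#' @param ... Unused.
#' @return The `per_step_means` tibble with the overall `lambda` attached
#'   as a column.
#' @method tidy ground_truth_rate
#' @export
tidy.ground_truth_rate <- function(x, ...) {
  dplyr::mutate(x$per_step_means, lambda = x$lambda_mm_per_year)
}

#' Tidy an error summary
#'
#' @param x A `ga_error_summary` from [summarize_errors()].
#' @param ... Unused.
#' @return The per-metric, per-interval error table.
#' @method tidy ga_error_summary
#' @export
tidy.ga_error_summary <- function(x, ...) {
  x$by_metric
}

#' One-line summary of a semisimulated ensemble
#'
#' @param x A `ga_ensemble` from [run_semisim()].
#' @param ... Unused.
#' @return A tibble with one row per follow-up interval: counts, mean
#'   and sd of ground-truth rates, mean absolute errors of both metrics,
#'   and their ratio.
#' @method glance ga_ensemble
#' @export
glance.ga_ensemble <- function(x, ...) {
  ok <- dplyr::filter(x, !is.na(.data$lambda))
  ok |>
    dplyr::group_by(.data$dt_years) |>
    dplyr::summarise(
      n = dplyr::n(),
      mu_lambda = mean(.data$lambda),
      sigma_lambda = stats::sd(.data$lambda),
      mu_e_er = mean(.data$e_er),
      mu_e_pa = mean(.data$e_pa),
      error_ratio = mean(.data$e_er) / mean(.data$e_pa),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_excluded = (nrow(x) - nrow(ok)) / dplyr::n_distinct(x$dt_years))
}
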