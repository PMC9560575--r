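#' Plot a lesion state, optionally over its growth field
#'
#' @param state A [lesion_state()].
#' @param field Optional [growth_field()] drawn as a raster underneath.
#' @return A ggplot.
#' @export
plot_lesion <- function(state, field = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(field)) {
    df <- expand.grid(x = grid_x(field$grid), y = grid_y(field$grid))
    df$v <- as.vector(field$values)
    p <- p +
      ggplot2::geom_raster(data = df, ggplot2::aes(.data$x, .data$y, fill = .data$v)) +
      ggplot2::scale_fill_viridis_c(name = "v (mm/yr)")
  }
  p +
    ggplot2::geom_path(data = contour_df(state$contours),
                       ggplot2::aes(.data$x, .data$y, group = .data$chain),
                       linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

contour_df <- function(cs, id_prefix = "") {
  purrr::imap(cs$chains, function(ch, k) {
    tibble::tibble(x = ch[, 1], y = ch[, 2],
                   chain = paste0(id_prefix, k),
                   is_hole = cs$is_hole[k])
  }) |> purrr::list_rbind()
}

#' Plot a margin sequence as nested contours coloured by time
#'
#' @param object A [margin_sequence()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot margin_sequence
#' @export
autoplot.margin_sequence <- function(object, ...) {
  df <- purrr::imap(object$states, function(st, k) {
    dplyr::mutate(contour_df(st$contours, id_prefix = paste0(k, ".")),
                  time_years = st$time_years)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$chain,
                                   colour = .data$time_years)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c(name = "t (yr)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a configuration sweep: estimates against ground truth
#'
#' Shows both length-type estimates against the measured ground-truth rate
#' per configuration, with the identity line and a half-pixel-per-year
#' accuracy band.
#'
#' @param object A `ga_sweep` from [run_config_sweep()].
#' @param band_mm_per_year Half-width of the accuracy band (default
#'   0.006 mm/year, half of the 12-micrometre pixel per year).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ga_sweep
#' @export
autoplot.ga_sweep <- function(object, band_mm_per_year = 0.006, ...) {
  ok <- dplyr::filter(object, .data$status == "ok")
  long <- tidyr::pivot_longer(
    dplyr::select(ok, "config_id", "lambda", "lambda_hat_er", "lambda_hat_pa"),
    c("lambda_hat_er", "lambda_hat_pa"),
    names_to = "metric", values_to = "estimate"
  )
  long$metric <- dplyr::recode(long$metric,
                               lambda_hat_er = "effective radius",
                               lambda_hat_pa = "perimeter adjusted")
  ggplot2::ggplot(long, ggplot2::aes(.data$lambda, .data$estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lambda - band_mm_per_year,
                   ymax = .data$lambda + band_mm_per_year),
      fill = "red", alpha = 0.25
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$metric)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$metric), size = 0.8) +
    ggplot2::facet_wrap(~config_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(Lambda ~ "(mm/yr)"),
                  y = expression(hat(Lambda) ~ "(mm/yr)")) +
    ggplot2::theme_minimal()
}

#' Plot a semisimulated ensemble: estimates against ground truth
#'
#' @param object A `ga_ensemble` from [run_semisim()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ga_ensemble
#' @export
autoplot.ga_ensemble <- function(object, ...) {
  ok <- dplyr::filter(object, !is.na(.data$lambda))
  long <- tidyr::pivot_longer(
    dplyr::select(ok, "dt_years", "lambda", "gini_focality_baseline",
                  "lambda_hat_er", "lambda_hat_pa"),
    c("lambda_hat_er", "lambda_hat_pa"),
    names_to = "metric", values_to = "estimate"
  )
  long$metric <- dplyr::recode(long$metric,
                               lambda_hat_er = "effective radius",
                               lambda_hat_pa = "perimeter adjusted")
  ggplot2::ggplot(long, ggplot2::aes(.data$lambda, .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$metric,
                                     size = .data$gini_focality_baseline),
                        alpha = 0.4) +
    ggplot2::scale_size_continuous(name = "Gini focality", range = c(0.3, 2.5)) +
    ggplot2::facet_grid(metric ~ dt_years, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(Lambda ~ "(mm/yr)"),
                  y = expression(hat(Lambda) ~ "(mm/yr)")) +
    ggplot2::theme_minimal()
}
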