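#' Length-type growth-rate estimators
#'
#' Global length-type growth-rate metrics estimate the ground-truth rate
#' `Lambda` (mm/year) from the baseline and follow-up margins only, the way
#' a clinic would:
#'
#' * **effective radius**: difference of equivalent-circle radii,
#'   `(sqrt(A_f/pi) - sqrt(A_b/pi)) / dt`;
#' * **square-root of area**: `(sqrt(A_f) - sqrt(A_b)) / dt`, i.e. the
#'   effective-radius rate scaled by `sqrt(pi)`;
#' * **perimeter-adjusted**: area change per unit time divided by the mean
#'   of the baseline and follow-up perimeters,
#'   `((A_f - A_b)/dt) / ((P_b + P_f)/2)`.
#'
#' All functions are vectorised over their arguments.
#'
#' @param area_baseline,area_followup Lesion areas, mm^2 (nonnegative).
#' @param dt_years Intervisit time, years (positive).
#' @return Growth-rate estimate(s), mm/year.
#' @examples
#' effective_radius_rate(pi, 1.21 * pi, 1)       # 0.1: circle r 1 -> 1.1
#' perimeter_adjusted_rate(pi, 1.21 * pi, 2 * pi, 2.2 * pi, 1)  # 0.1 exactly
#' @export
effective_radius_rate <- function(area_baseline, area_followup, dt_years) {
  check_metric_inputs(area_baseline, area_followup, dt_years)
  (sqrt(area_followup / pi) - sqrt(area_baseline / pi)) / dt_years
}

#' @rdname effective_radius_rate
#' @export
sqrt_area_rate <- function(area_baseline, area_followup, dt_years) {
  sqrt(pi) * effective_radius_rate(area_baseline, area_followup, dt_years)
}

#' @rdname effective_radius_rate
#' @param perimeter_baseline,perimeter_followup Lesion perimeters, mm; their
#'   mean must be positive.
#' @export
perimeter_adjusted_rate <- function(area_baseline, area_followup,
                                    perimeter_baseline, perimeter_followup,
                                    dt_years) {
  check_metric_inputs(area_baseline, area_followup, dt_years)
  pm <- (perimeter_baseline + perimeter_followup) / 2
  if (any(!is.finite(pm)) || any(pm <= 0)) {
    stop("mean perimeter must be positive", call. = FALSE)
  }
  ((area_followup - area_baseline) / dt_years) / pm
}

check_metric_inputs <- function(a_b, a_f, dt) {
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    stop("dt_years must be positive", call. = FALSE)
  }
  if (any(!is.finite(a_b)) || any(!is.finite(a_f)) || any(a_b < 0) || any(a_f < 0)) {
    stop("areas must be finite and nonnegative", call. = FALSE)
  }
  invisible(TRUE)
}

#' Predicted small-growth bias of the effective-radius metric
#'
#' In the limit of growth small relative to the baseline perimeter and
#' area, the effective-radius estimate overshoots the true length-type rate
#' by the factor `1 / sqrt(circ)`, where `circ = 4*pi*A/P^2` is the
#' baseline circularity. For `n` equal circular foci `circ = 1/n`, so the
#' factor reduces to `sqrt(n)`.
#'
#' @param circularity Baseline circularity, in (0, 1].
#' @return The predicted ratio of the effective-radius estimate to the
#'   ground-truth rate (dimensionless, >= 1).
#' @examples
#' predicted_er_bias(1)      # 1: no bias for a circle
#' predicted_er_bias(1 / 4)  # 2: four equal foci
#' @export
predicted_er_bias <- function(circularity) {
  if (any(!is.finite(circularity)) || any(circularity <= 0) ||
      any(circularity > 1)) {
    stop("circularity must be in (0, 1]", call. = FALSE)
  }
  1 / sqrt(circularity)
}

#' Compute all length-type metrics for a table of margin-pair measurements
#'
#' Data-frame-first interface: takes one row per baseline/follow-up margin
#' pair and appends the three estimates.
#'
#' @param data A data frame with columns `area_baseline`, `area_followup`,
#'   `perimeter_baseline`, `perimeter_followup`, `dt_years`.
#' @return The input as a [tibble::tibble()] with added columns
#'   `lambda_hat_er`, `lambda_hat_sqrt_area`, `lambda_hat_pa` (mm/year).
#' @examples
#' growth_metrics(tibble::tibble(
#'   area_baseline = pi, area_followup = 1.21 * pi,
#'   perimeter_baseline = 2 * pi, perimeter_followup = 2.2 * pi,
#'   dt_years = 1
#' ))
#' @export
growth_metrics <- function(data) {
  need <- c("area_baseline", "area_followup", "perimeter_baseline",
            "perimeter_followup", "dt_years")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    lambda_hat_er = effective_radius_rate(
      .data$area_baseline, .data$area_followup, .data$dt_years),
    lambda_hat_sqrt_area = sqrt_area_rate(
      .data$area_baseline, .data$area_followup, .data$dt_years),
    lambda_hat_pa = perimeter_adjusted_rate(
      .data$area_baseline, .data$area_followup,
      .data$perimeter_baseline, .data$perimeter_followup, .data$dt_years)
  )
}

#' Length-type metrics from a pair of lesion states
#'
#' Mimics the clinical measurement: only the baseline and follow-up margins
#' are used. Descriptors are computed from the subpixel contours.
#'
#' @param baseline,followup [lesion_state()] objects.
#' @param dt_years Intervisit time; defaults to the difference of the two
#'   states' time stamps.
#' @return A one-row tibble with baseline/follow-up descriptors and the
#'   three estimates.
#' @export
lesion_metrics <- function(baseline, followup, dt_years = NULL) {
  stopifnot(inherits(baseline, "lesion_state"), inherits(followup, "lesion_state"))
  if (is.null(dt_years)) dt_years <- followup$time_years - baseline$time_years
  db <- shape_descriptors(baseline)
  df <- shape_descriptors(followup)
  growth_metrics(tibble::tibble(
    area_baseline = db$area_mm2,
    area_followup = df$area_mm2,
    perimeter_baseline = db$perimeter_mm,
    perimeter_followup = df$perimeter_mm,
    dt_years = dt_years,
    circularity_baseline = db$circularity,
    focality_baseline = db$focality,
    gini_focality_baseline = db$gini_focality
  ))
}
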