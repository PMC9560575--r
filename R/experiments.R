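#' Growth-rate sweep over the benchmark configurations
#'
#' For each requested configuration and each target ground-truth rate, the
#' growth field is rescaled (the baseline geometry is untouched), the
#' margin is propagated for `dt_years`, and the length-type metrics are
#' computed from the baseline and follow-up margins only. The measured
#' ground truth `lambda` is reported alongside the target.
#'
#' @param config_ids Subset of 1-8.
#' @param lambda_grid Target rates, mm/year, within `[0.05, 0.7]`.
#' @param dt_years Follow-up interval, years.
#' @param pixel_size_mm Simulation resolution.
#' @param n_steps Propagation steps per simulation.
#' @param pad_mm Grid padding; defaults to the maximal swept growth plus
#'   0.5 mm so no cell is clipped.
#' @return A tibble of class `ga_sweep`, one row per (config, lambda):
#'   measured ground truth, the three metric estimates, absolute errors,
#'   and a `status` column (`"ok"` or the failure reason; failed cells keep
#'   `NA` estimates rather than being dropped).
#' @export
run_config_sweep <- function(config_ids = 1:8,
                             lambda_grid = c(0.05, 0.1, 0.2, 0.4, 0.7),
                             dt_years = 1, pixel_size_mm = 0.012,
                             n_steps = 10,
                             pad_mm = max(lambda_grid) * dt_years + 0.5) {
  stopifnot(all(config_ids %in% 1:8),
            all(lambda_grid >= 0.05 - 1e-12), all(lambda_grid <= 0.7 + 1e-12))
  rows <- purrr::map(config_ids, function(id) {
    cfg <- make_config(id, pixel_size_mm = pixel_size_mm, pad_mm = pad_mm,
                       dt_years = dt_years, n_steps = n_steps)
    purrr::map(lambda_grid, function(lam) {
      res <- tryCatch({
        f <- scale_field_to_lambda(cfg$baseline, cfg$field, dt_years, lam,
                                   n_steps = n_steps)
        sq <- propagate(cfg$baseline, f, dt_years, n_steps)
        gt <- ground_truth_lambda(sq)$lambda_mm_per_year
        est <- lesion_metrics(sq$states[[1]], sq$states[[length(sq$states)]],
                              dt_years)
        dplyr::mutate(est, lambda = gt, status = "ok")
      }, error = function(e) {
        tibble::tibble(lambda = NA_real_, status = conditionMessage(e))
      })
      dplyr::mutate(res, config_id = id, lambda_target = lam, .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out <- dplyr::mutate(
    rows,
    e_er = abs(.data$lambda_hat_er - .data$lambda),
    e_pa = abs(.data$lambda_hat_pa - .data$lambda)
  )
  class(out) <- c("ga_sweep", class(out))
  out
}

#' Semisimulated growth ensemble
#'
#' Runs the factorial ensemble of random baseline lesions times random
#' growth fields times follow-up intervals: each baseline is propagated
#' under each field (one eikonal solve per pair, thresholded at every
#' interval), the ground truth `Lambda` is measured from the margin
#' sequence, and the metrics are computed from the baseline/follow-up
#' margin pair only. Cells whose growth would clip the grid are recorded
#' with a `status` reason rather than silently dropped.
#'
#' @param n_lesions Number of random baseline lesions.
#' @param n_fields_per_lesion Random growth fields per lesion.
#' @param dts Follow-up intervals, years.
#' @param params A calibrated [random_field_params()]; defaults to the
#'   clinical-like targets of [random_field_params()].
#' @param master_seed Integer; the whole table is reproducible from it
#'   (per-lesion and per-field seeds are derived streams).
#' @param pixel_size_mm Simulation resolution (default 24 micrometres for
#'   ensemble work).
#' @param fov_mm Field of view, mm.
#' @param pad_mm Grid padding; defaults to generous headroom for the
#'   largest interval.
#' @param gen_params A [lesion_gen_params()].
#' @param lesions Optional list of [lesion_state()] baselines on a common
#'   grid (e.g. the cohort used to calibrate `params`); when supplied,
#'   `n_lesions` and the grid arguments are ignored and no lesions are
#'   sampled. This mirrors the semisimulated design: one fixed cohort of
#'   baselines, many random fields.
#' @param n_steps Propagation steps per interval.
#' @return A tibble of class `ga_ensemble`: one row per (lesion, field,
#'   dt) with baseline descriptors, `lambda`, the estimates, absolute
#'   errors, and `status`.
#' @export
run_semisim <- function(n_lesions = 10, n_fields_per_lesion = 20, dts = 1,
                        params = random_field_params(), master_seed = 1,
                        pixel_size_mm = 0.024, fov_mm = 6,
                        pad_mm = NULL, gen_params = lesion_gen_params(),
                        lesions = NULL, n_steps = 10) {
  if (!is.null(lesions)) n_lesions <- length(lesions)
  stopifnot(n_lesions >= 1, n_fields_per_lesion >= 1, all(dts > 0))
  if (is.null(lesions)) {
    if (is.null(pad_mm)) {
      pad_mm <- max(dts) * (params$global_scale_mean + 3 * params$global_scale_sd) + 0.5
    }
    grid <- pixel_grid_centered(fov_mm + 2 * pad_mm, pixel_size_mm)
  } else {
    grid <- lesions[[1]]$grid
  }
  seeds <- withr::with_seed(as.integer(master_seed), {
    list(
      lesion = sample.int(.Machine$integer.max - 1, n_lesions),
      field = matrix(sample.int(.Machine$integer.max - 1,
                                n_lesions * n_fields_per_lesion),
                     n_lesions, n_fields_per_lesion),
      # stratified gamma quantiles per lesion: the ensemble mean of the
      # global scale carries no sampling noise, the marginal law is intact
      gq = {
        m <- matrix(0, n_lesions, n_fields_per_lesion)
        for (i in seq_len(n_lesions)) {
          m[i, ] <- (sample(n_fields_per_lesion) -
                       stats::runif(n_fields_per_lesion)) / n_fields_per_lesion
        }
        m
      }
    )
  })
  rows <- purrr::map(seq_len(n_lesions), function(li) {
    lesion <- if (is.null(lesions)) {
      sample_baseline_lesion(gen_params, grid, seeds$lesion[li])
    } else {
      lesions[[li]]
    }
    d <- attr(lesion, "descriptors")
    if (is.null(d)) d <- shape_descriptors(lesion)
    purrr::map(seq_len(n_fields_per_lesion), function(fi) {
      f <- make_growth_field(params, grid, seeds$field[li, fi],
                             global_quantile = seeds$gq[li, fi])
      at <- arrival_time(lesion, f)
      purrr::map(dts, function(dt) {
        res <- tryCatch({
          sq <- propagate_arrival(at, dt, n_steps)
          gt <- ground_truth_lambda(sq)$lambda_mm_per_year
          est <- lesion_metrics(sq$states[[1]], sq$states[[length(sq$states)]], dt)
          tibble::tibble(
            lambda = gt,
            lambda_hat_er = est$lambda_hat_er,
            lambda_hat_sqrt_area = est$lambda_hat_sqrt_area,
            lambda_hat_pa = est$lambda_hat_pa,
            status = "ok"
          )
        }, error = function(e) {
          tibble::tibble(lambda = NA_real_, lambda_hat_er = NA_real_,
                         lambda_hat_sqrt_area = NA_real_,
                         lambda_hat_pa = NA_real_,
                         status = conditionMessage(e))
        })
        dplyr::mutate(res, lesion_id = li, field_id = fi, dt_years = dt,
                      area_baseline = d$area_mm2,
                      perimeter_baseline = d$perimeter_mm,
                      circularity_baseline = d$circularity,
                      focality_baseline = d$focality,
                      gini_focality_baseline = d$gini_focality,
                      .before = 1)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out <- dplyr::mutate(
    rows,
    e_er = abs(.data$lambda_hat_er - .data$lambda),
    e_pa = abs(.data$lambda_hat_pa - .data$lambda)
  )
  attr(out, "params") <- params
  attr(out, "master_seed") <- master_seed
  class(out) <- c("ga_ensemble", class(out))
  out
}

#' Summarize metric errors of an ensemble
#'
#' Produces, per metric and follow-up interval: the mean and sd of the
#' absolute estimation errors, error percentiles, the representative
#' simulations at the 25th/50th/75th/100th percentiles of the
#' perimeter-adjusted error, and per-lesion mean errors against the
#' baseline descriptors together with the small-growth analytic bias
#' prediction for the effective-radius metric
#' (`Lambda * (1/sqrt(circ) - 1)`).
#'
#' @param table A `ga_ensemble` (or any table with the same columns).
#' @return An object of class `ga_error_summary`: list with `by_metric`,
#'   `percentile_cases`, `per_lesion`, and `n_excluded` (failed cells).
#' @export
summarize_errors <- function(table) {
  need <- c("dt_years", "lambda", "e_er", "e_pa")
  stopifnot(all(need %in% names(table)))
  tab <- dplyr::filter(table, !is.na(.data$lambda))
  if (nrow(tab) == 0) stop("no successful simulations to summarize", call. = FALSE)
  n_excluded <- nrow(table) - nrow(tab)

  long <- tidyr::pivot_longer(
    dplyr::select(tab, "dt_years", "e_er", "e_pa"),
    c("e_er", "e_pa"), names_to = "metric", values_to = "e"
  )
  long$metric <- dplyr::recode(long$metric,
                               e_er = "effective_radius",
                               e_pa = "perimeter_adjusted")
  by_metric <- long |>
    dplyr::group_by(.data$metric, .data$dt_years) |>
    dplyr::summarise(
      n = dplyr::n(),
      mu_e = mean(.data$e),
      sigma_e = stats::sd(.data$e),
      p50 = stats::quantile(.data$e, 0.50, names = FALSE),
      p90 = stats::quantile(.data$e, 0.90, names = FALSE),
      p95 = stats::quantile(.data$e, 0.95, names = FALSE),
      .groups = "drop"
    )

  percentile_cases <- tab |>
    dplyr::group_by(.data$dt_years) |>
    dplyr::group_modify(function(df, key) {
      qs <- c(0.25, 0.50, 0.75, 1.00)
      purrr::map(qs, function(q) {
        target <- stats::quantile(df$e_pa, q, names = FALSE)
        row <- df[which.min(abs(df$e_pa - target)), ]
        dplyr::mutate(row, percentile = 100 * q, .before = 1)
      }) |> purrr::list_rbind()
    }) |>
    dplyr::ungroup()

  per_lesion <- NULL
  if (all(c("lesion_id", "circularity_baseline") %in% names(tab))) {
    per_lesion <- tab |>
      dplyr::group_by(.data$lesion_id, .data$dt_years) |>
      dplyr::summarise(
        n = dplyr::n(),
        area_baseline = .data$area_baseline[1],
        perimeter_baseline = .data$perimeter_baseline[1],
        circularity_baseline = .data$circularity_baseline[1],
        focality_baseline = .data$focality_baseline[1],
        gini_focality_baseline = .data$gini_focality_baseline[1],
        mean_lambda = mean(.data$lambda),
        mean_e_er = mean(.data$e_er),
        mean_e_pa = mean(.data$e_pa),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        predicted_e_er = .data$mean_lambda *
          (predicted_er_bias(.data$circularity_baseline) - 1)
      )
  }

  structure(
    list(by_metric = by_metric, percentile_cases = percentile_cases,
         per_lesion = per_lesion, n_excluded = n_excluded),
    class = "ga_error_summary"
  )
}

#' @export
print.ga_error_summary <- function(x, ...) {
  cat("<ga_error_summary>\n")
  print(x$by_metric)
  if (x$n_excluded > 0) cat(x$n_excluded, "cell(s) excluded (clipped/failed)\n")
  invisible(x)
}
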