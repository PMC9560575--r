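test_that("config sweep recovers the target rates on simple configurations", {
  sw <- run_config_sweep(config_ids = c(1, 5), lambda_grid = c(0.1, 0.4),
                         pixel_size_mm = 0.024)
  expect_s3_class(sw, "ga_sweep")
  expect_identical(nrow(sw), 4L)
  expect_true(all(sw$status == "ok"))
  expect_lt(max(abs(sw$lambda - sw$lambda_target)), 1e-3)
  # perimeter-adjusted exact within half a pixel per year everywhere
  expect_lt(max(sw$e_pa), 0.5 * 0.024)
  # effective radius: exact on the circle, sqrt(2)-inflated on two foci
  expect_lt(max(sw$e_er[sw$config_id == 1]), 0.5 * 0.024)
  er5 <- sw[sw$config_id == 5, ]
  expect_lt(max(abs(er5$lambda_hat_er - sqrt(2) * er5$lambda)), 0.01 * sqrt(2) * 0.4)
})

test_that("semisimulated ensembles are reproducible and complete", {
  e1 <- run_semisim(n_lesions = 2, n_fields_per_lesion = 3, dts = 1,
                    master_seed = 5, pixel_size_mm = 0.048)
  e2 <- run_semisim(n_lesions = 2, n_fields_per_lesion = 3, dts = 1,
                    master_seed = 5, pixel_size_mm = 0.048)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_identical(nrow(e1), 6L)
  expect_true(all(e1$e_er[!is.na(e1$lambda)] >= 0))
  expect_true(all(c("lesion_id", "field_id", "dt_years", "lambda",
                    "lambda_hat_er", "lambda_hat_pa", "status") %in% names(e1)))
})

test_that("a supplied baseline cohort is used as-is", {
  g <- pixel_grid_centered(4, 0.04)
  les <- list(
    rasterize(shape_disk(c(0, 0), 0.6), g),
    rasterize(shape_union(shape_disk(c(-0.7, 0), 0.4),
                          shape_disk(c(0.7, 0), 0.4)), g)
  )
  p <- random_field_params(pointwise_sd = 0.02)
  ens <- run_semisim(n_fields_per_lesion = 2, dts = 1, params = p,
                     master_seed = 9, lesions = les)
  expect_identical(nrow(ens), 4L)
  expect_identical(ens$focality_baseline[ens$lesion_id == 2][1], 2L)
})

test_that("clipped cells are recorded with a reason, not dropped", {
  g <- pixel_grid_centered(2.2, 0.04)
  les <- list(rasterize(shape_disk(c(0, 0), 0.8), g))
  p <- random_field_params(pointwise_mean = 0.2, pointwise_sd = 0)
  ens <- run_semisim(n_fields_per_lesion = 2, dts = c(5), params = p,
                     master_seed = 1, lesions = les)
  expect_identical(nrow(ens), 2L)
  expect_true(all(is.na(ens$lambda)))
  expect_true(all(grepl("border", ens$status)))
  expect_error(summarize_errors(ens), "no successful")
})

test_that("error summaries reduce a known table correctly", {
  tab <- tibble::tibble(
    lesion_id = rep(1:2, each = 4),
    field_id = rep(1:4, 2),
    dt_years = 1,
    area_baseline = 5, perimeter_baseline = 10,
    circularity_baseline = 0.5, focality_baseline = 2L,
    gini_focality_baseline = 2,
    lambda = 0.1,
    lambda_hat_er = 0.1 + c(0.01, 0.02, 0.03, 0.04, 0.01, 0.02, 0.03, 0.04),
    lambda_hat_pa = 0.1,
    status = "ok"
  )
  tab$e_er <- abs(tab$lambda_hat_er - tab$lambda)
  tab$e_pa <- abs(tab$lambda_hat_pa - tab$lambda)
  s <- summarize_errors(tab)
  pa <- s$by_metric[s$by_metric$metric == "perimeter_adjusted", ]
  expect_equal(pa$mu_e, 0)
  expect_equal(pa$sigma_e, 0)
  er <- s$by_metric[s$by_metric$metric == "effective_radius", ]
  expect_equal(er$mu_e, 0.025)
  # the 100th-percentile representative case carries the maximal error
  top <- s$percentile_cases[s$percentile_cases$percentile == 100, ]
  expect_equal(top$e_pa, max(tab$e_pa))
  # per-lesion analytic bias prediction uses 1/sqrt(circ) - 1
  expect_equal(s$per_lesion$predicted_e_er,
               rep(0.1 * (1 / sqrt(0.5) - 1), 2), tolerance = 1e-12)
  expect_identical(s$n_excluded, 0L)
})

test_that("tidiers and plot builders return well-formed objects", {
  g <- small_grid(3, 0.03)
  st <- rasterize(shape_disk(c(0, 0), 0.8), g)
  sq <- propagate(st, growth_field(g, 0.1), 1, 4)
  td <- tidy(sq)
  expect_identical(nrow(td), 5L)
  expect_true(all(diff(td$area_mm2) > 0))
  gt <- ground_truth_lambda(sq)
  expect_identical(nrow(tidy(gt)), 5L)
  expect_s3_class(autoplot(sq), "ggplot")
  expect_s3_class(plot_lesion(st, growth_field(g, 0.1)), "ggplot")

  ens <- run_semisim(n_lesions = 1, n_fields_per_lesion = 2, dts = 1,
                     master_seed = 2, pixel_size_mm = 0.048)
  gl <- glance(ens)
  expect_identical(nrow(gl), 1L)
  expect_s3_class(autoplot(ens), "ggplot")
})
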