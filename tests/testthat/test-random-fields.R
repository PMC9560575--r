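grf_grid <- pixel_grid(250, 250, pixel_size_mm = 0.02)

test_that("unit GRF is deterministic, zero-mean, unit-variance", {
  z1 <- sample_unit_grf(grf_grid, 0.1, 42)
  z2 <- sample_unit_grf(grf_grid, 0.1, 42)
  expect_identical(z1, z2)

  stats <- vapply(1:20, function(s) {
    z <- sample_unit_grf(grf_grid, 0.1, s)
    c(mean(z), stats::var(as.vector(z)))
  }, numeric(2))
  # corr length (0.1 mm) is tiny relative to the 5 mm extent, so the
  # domain averages are tight
  expect_lt(abs(mean(stats[1, ])), 3 * stats::sd(stats[1, ]) / sqrt(20) + 5e-3)
  expect_lt(abs(mean(stats[2, ]) - 1), 0.1)
})

test_that("GRF spatial correlation decays at the requested scale", {
  z <- sample_unit_grf(grf_grid, 0.1, 99)
  lag <- 5  # one correlation length = 5 pixels
  cc <- stats::cor(as.vector(z[seq_len(250 - lag), ]),
                   as.vector(z[seq_len(250 - lag) + lag, ]))
  expect_lt(abs(cc - exp(-0.5)), 0.08)
})

test_that("sub-resolution correlation lengths are rejected", {
  expect_error(sample_unit_grf(grf_grid, 0.03, 1), "2 pixels")
})

test_that("growth fields are nonnegative, reproducible, mean-correct", {
  p <- random_field_params()
  f1 <- make_growth_field(p, grf_grid, 7)
  f2 <- make_growth_field(p, grf_grid, 7)
  expect_identical(f1$values, f2$values)
  expect_gte(min(f1$values), 0)

  # degenerate parameters give the constant isotropic field
  p0 <- random_field_params(pointwise_mean = 0.1, pointwise_sd = 0)
  f0 <- make_growth_field(p0, grf_grid, 1)
  expect_equal(max(abs(f0$values - 0.1)), 0)

  # unbiasedness of the mean-corrected log-normal: pointwise mean over
  # stratified global draws approaches the nominal mean
  means <- vapply(1:60, function(s) {
    mean(make_growth_field(p, grf_grid, s,
                           global_quantile = (s - 0.5) / 60)$values)
  }, numeric(1))
  expect_lt(abs(mean(means) - p$global_scale_mean) / p$global_scale_mean, 0.1)
})

test_that("parameter derivation hits the pointwise moment targets", {
  p <- random_field_params(pointwise_mean = 0.1, pointwise_sd = 0.1,
                           global_frac = 0.5)
  m <- p$global_scale_mean
  vg <- p$global_scale_sd^2
  vtot <- (m^2 + vg) * exp(p$local_sd_log^2) - m^2
  expect_equal(m, 0.1)
  expect_equal(vtot, 0.01, tolerance = 1e-12)
})

test_that("calibration leaves a degenerate isotropic generator untouched", {
  g <- small_grid(3, h = 0.05)
  st <- rasterize(shape_disk(c(0, 0), 0.7), g)
  p0 <- random_field_params(pointwise_mean = 0.1, pointwise_sd = 0)
  p <- calibrate_ensemble(list(st), p0, dt_years = 1, target_mean = 0.1,
                          n_pilot = 50, seed = 3)
  expect_equal(p$global_scale_mean, 0.1)
  ach <- attr(p, "achieved")
  expect_equal(unname(ach["mu_lambda"]), 0.1, tolerance = 1e-6)
})

test_that("calibration corrects a mis-scaled generator to the target mean", {
  g <- small_grid(3, h = 0.05)
  st <- rasterize(shape_disk(c(0, 0), 0.7), g)
  p0 <- random_field_params(pointwise_mean = 0.05, pointwise_sd = 0.02)
  p <- calibrate_ensemble(list(st), p0, dt_years = 1, target_mean = 0.1,
                          n_pilot = 50, seed = 5, tol = 0.05)
  ach <- attr(p, "achieved")
  expect_lt(abs(ach["mu_lambda"] - 0.1) / 0.1, 0.05)
  expect_gt(p$global_scale_mean, p0$global_scale_mean)
})
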