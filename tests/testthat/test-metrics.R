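test_that("effective radius rate reproduces its closed-form circle values", {
  expect_equal(effective_radius_rate(pi, 1.21 * pi, 1), 0.1, tolerance = 1e-12)
  expect_equal(effective_radius_rate(2.5, 2.5, 1), 0)
  # two equal circles r 1 -> 1.1: sqrt(2.42) - sqrt(2) = sqrt(2) * 0.1
  expect_equal(effective_radius_rate(2 * pi, 2.42 * pi, 1), sqrt(2) * 0.1,
               tolerance = 1e-12)
  expect_error(effective_radius_rate(1, 2, 0), "positive")
  expect_error(effective_radius_rate(-1, 2, 1), "nonnegative")
})

test_that("sqrt-area rate is the sqrt(pi)-scaled effective radius rate", {
  expect_equal(sqrt_area_rate(pi, 1.21 * pi, 1), 0.1 * sqrt(pi),
               tolerance = 1e-12)
  set.seed(2)
  ab <- runif(20, 0.5, 8)
  af <- ab + runif(20, 0, 3)
  dt <- runif(20, 0.5, 5)
  expect_equal(sqrt_area_rate(ab, af, dt) / effective_radius_rate(ab, af, dt),
               rep(sqrt(pi), 20), tolerance = 1e-12)
})

test_that("perimeter-adjusted rate is algebraically exact for concentric circles", {
  set.seed(3)
  for (k in 1:10) {
    r <- runif(1, 0.3, 2)
    r2 <- r + runif(1, 0.01, 1)
    dt <- runif(1, 0.5, 5)
    est <- perimeter_adjusted_rate(pi * r^2, pi * r2^2, 2 * pi * r, 2 * pi * r2, dt)
    expect_equal(est, (r2 - r) / dt, tolerance = 1e-12)
  }
  # two equal circles: areas and perimeters double, estimate unchanged
  expect_equal(
    perimeter_adjusted_rate(2 * pi, 2 * 1.21 * pi, 4 * pi, 4.4 * pi, 1),
    0.1, tolerance = 1e-12
  )
  expect_equal(perimeter_adjusted_rate(3, 3, 5, 5, 2), 0)
  expect_error(perimeter_adjusted_rate(1, 2, 0, 0, 1), "perimeter")
})

test_that("predicted effective-radius bias follows 1/sqrt(circularity)", {
  expect_equal(predicted_er_bias(1), 1)
  for (n in 2:4) {
    expect_equal(predicted_er_bias(1 / n), sqrt(n), tolerance = 1e-12)
  }
  expect_equal(predicted_er_bias(0.841), 1 / sqrt(0.841), tolerance = 1e-12)
  expect_lt(abs(predicted_er_bias(0.841) - 1.090), 0.001)
  expect_error(predicted_er_bias(0))
  expect_error(predicted_er_bias(1.2))
})

test_that("growth_metrics computes all three estimators on a table", {
  tab <- tibble::tibble(
    area_baseline = c(pi, 2 * pi),
    area_followup = c(1.21 * pi, 2.42 * pi),
    perimeter_baseline = c(2 * pi, 4 * pi),
    perimeter_followup = c(2.2 * pi, 4.4 * pi),
    dt_years = 1
  )
  out <- growth_metrics(tab)
  expect_equal(out$lambda_hat_er, c(0.1, sqrt(2) * 0.1), tolerance = 1e-12)
  expect_equal(out$lambda_hat_pa, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(out$lambda_hat_sqrt_area, sqrt(pi) * out$lambda_hat_er,
               tolerance = 1e-12)
  expect_error(growth_metrics(tab[, -1]), "missing columns")
})

test_that("lesion_metrics agrees with the scalar form on rasterized disks", {
  g <- small_grid(4, h = 0.015)
  b <- rasterize(shape_disk(c(0, 0), 1), g, time_years = 0)
  f <- rasterize(shape_disk(c(0, 0), 1.1), g, time_years = 1)
  m <- lesion_metrics(b, f)
  expect_equal(m$dt_years, 1)
  expect_lt(abs(m$lambda_hat_er - 0.1), 5e-4)
  expect_lt(abs(m$lambda_hat_pa - 0.1), 5e-4)
  expect_lt(abs(m$circularity_baseline - 1), 0.01)
})
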