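# shared fixture: disk baseline on a 30-um grid
fix_grid <- small_grid(4, h = 0.03)
fix_disk <- rasterize(shape_disk(c(0, 0), 1), fix_grid)

test_that("constant-speed arrival times equal distance over speed", {
  v <- 0.1
  at <- arrival_time(fix_disk, growth_field(fix_grid, v))
  xs <- grid_x(fix_grid)
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  sel <- rr > 1 + 5 * 0.03 & rr < 1.8
  err <- at$times[sel] - (rr[sel] - 1) / v
  expect_lt(max(abs(err)) * v, 0.5 * 0.03)  # within half a pixel of distance
})

test_that("an impermeable (v = 0) field leaves the lesion unchanged", {
  sq <- propagate(fix_disk, growth_field(fix_grid, 0), dt_years = 3, n_steps = 4)
  areas <- vapply(sq$states, function(s) contour_area(s$contours), numeric(1))
  # areas agree to far below one pixel (contours are re-extracted per state)
  expect_lt(max(abs(areas - areas[1])), 0.03^2 * 1e-3)
  expect_identical(sq$states[[5]]$mask, fix_disk$mask)
})

test_that("a disk under isotropic growth becomes the enlarged concentric disk", {
  sq <- propagate(fix_disk, growth_field(fix_grid, 0.1), 1, 10)
  a_f <- contour_area(sq$states[[11]]$contours)
  expect_lt(abs(a_f - 1.21 * pi) / (1.21 * pi), 0.005)
  # radius error below one pixel
  expect_lt(abs(sqrt(a_f / pi) - 1.1), 0.03)
})

test_that("margin sequences are nested with nondecreasing areas", {
  vals <- withr::with_seed(3, {
    z <- sample_unit_grf(fix_grid, 0.4, 11)
    0.08 * exp(0.4 * z - 0.08)
  })
  sq <- propagate(fix_disk, growth_field(fix_grid, vals), 1, 8)
  areas <- vapply(sq$states, function(s) contour_area(s$contours), numeric(1))
  expect_true(all(diff(areas) >= -1e-9))
  for (k in seq_len(length(sq$states) - 1)) {
    expect_false(any(sq$states[[k]]$mask & !sq$states[[k + 1]]$mask))
  }
})

test_that("pointwise larger fields produce supersets of lesions", {
  v1 <- withr::with_seed(4, abs(sample_unit_grf(fix_grid, 0.5, 21)) * 0.05 + 0.02)
  v2 <- v1 + 0.05
  m1 <- propagate(fix_disk, growth_field(fix_grid, v1), 1, 2)$states[[3]]$mask
  m2 <- propagate(fix_disk, growth_field(fix_grid, v2), 1, 2)$states[[3]]$mask
  expect_false(any(m1 & !m2))
})

test_that("close foci merge into a single component during growth", {
  st <- rasterize(
    shape_union(shape_disk(c(-0.55, 0), 0.5), shape_disk(c(0.55, 0), 0.5)),
    fix_grid
  )  # edge-to-edge gap 0.1 mm
  expect_identical(shape_descriptors(st)$focality, 2L)
  sq <- propagate(st, growth_field(fix_grid, 0.1), 1, 5)
  expect_identical(shape_descriptors(sq$states[[6]])$focality, 1L)
})

test_that("ground-truth rate is exact for constant fields", {
  sq <- propagate(fix_disk, growth_field(fix_grid, 0.1), 1, 10)
  gt <- ground_truth_lambda(sq)
  expect_equal(gt$lambda_mm_per_year, 0.1, tolerance = 1e-10)
  # bracketing by the per-step means
  expect_gte(gt$lambda_mm_per_year, min(gt$per_step_means$mean_speed) - 1e-12)
  expect_lte(gt$lambda_mm_per_year, max(gt$per_step_means$mean_speed) + 1e-12)
})

test_that("two-focus ground truth matches the closed-form arclength average", {
  g <- small_grid(6, h = 0.03)
  rA <- 0.6
  rB <- 0.6
  vA <- 0.05
  vB <- 0.1
  cA <- c(-1.5, 0)
  cB <- c(1.5, 0)
  st <- rasterize(shape_union(shape_disk(cA, rA), shape_disk(cB, rB)), g)
  vals <- outer(grid_x(g), grid_y(g), function(x, y) ifelse(x < 0, vA, vB))
  sq <- propagate(st, growth_field(g, vals), 1, 10)
  gt <- ground_truth_lambda(sq)$lambda_mm_per_year
  # oracle: margins stay concentric circles, radii r + v t at saved times
  tk <- seq(0, 1, length.out = 11)
  oracle <- sum(2 * pi * (rA + vA * tk) * vA + 2 * pi * (rB + vB * tk) * vB) /
    sum(2 * pi * (rA + vA * tk) + 2 * pi * (rB + vB * tk))
  expect_lt(abs(gt - oracle) / oracle, 0.01)
})

test_that("scaling the field scales the ground-truth rate exactly", {
  th <- outer(grid_x(fix_grid), grid_y(fix_grid), function(x, y) atan2(y, x))
  vals <- 0.08 * (1 + 0.6 * cos(2 * th))
  lam1 <- ground_truth_lambda(
    propagate(fix_disk, growth_field(fix_grid, vals), 1, 6))$lambda_mm_per_year
  lam2 <- ground_truth_lambda(
    propagate(fix_disk, growth_field(fix_grid, 2.5 * vals), 0.4, 6))$lambda_mm_per_year
  # same margins at the same relative times: exact linearity
  expect_equal(lam2, 2.5 * lam1, tolerance = 1e-9)
})

test_that("scale_field_to_lambda is exact for isotropic fields and converges otherwise", {
  f <- scale_field_to_lambda(fix_disk, growth_field(fix_grid, 0.1), 1, 0.2)
  expect_equal(max(abs(f$values - 0.2)), 0, tolerance = 1e-12)

  th <- outer(grid_x(fix_grid), grid_y(fix_grid), function(x, y) atan2(y, x))
  fa <- growth_field(fix_grid, 0.1 * (1 + 0.8 * cos(2 * th)))
  fs <- scale_field_to_lambda(fix_disk, fa, 1, 0.15)
  lam <- ground_truth_lambda(propagate(fix_disk, fs, 1, 10))$lambda_mm_per_year
  expect_lt(abs(lam - 0.15), 1e-3)

  expect_error(scale_field_to_lambda(fix_disk, fa, 1, 0), "positive")
  expect_error(
    scale_field_to_lambda(fix_disk, growth_field(fix_grid, 0), 1, 0.1),
    "zero"
  )
})

test_that("propagation that would clip the grid border errors out", {
  g <- small_grid(2.4, h = 0.03)
  st <- rasterize(shape_disk(c(0, 0), 0.9), g)
  expect_error(propagate(st, growth_field(g, 0.2), 2, 4), "border")
})

test_that("arrival-time and level-set propagators agree within one pixel", {
  for (id in c(1, 3)) {
    cfg <- make_config(id, pixel_size_mm = 0.032)
    fm <- propagate(cfg$baseline, cfg$field, 1, 4)$states[[5]]$mask
    ls <- level_set_propagate(cfg$baseline, cfg$field, 1)
    expect_lte(hausdorff_mask(fm, ls$mask, 1), 1 + 1e-9)
  }
})
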