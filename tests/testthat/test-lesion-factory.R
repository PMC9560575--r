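# shared fixture: all eight configurations at working resolution
cfgs <- lapply(1:8, make_config, pixel_size_mm = 0.024)

test_that("every configuration meets its area and rate contract", {
  for (cfg in cfgs) {
    d <- shape_descriptors(cfg$baseline)
    expect_lt(abs(d$area_mm2 - 6) / 6, 0.005)
    lam <- ground_truth_lambda(
      propagate(cfg$baseline, cfg$field, cfg$dt_years, 10))$lambda_mm_per_year
    expect_lt(abs(lam - 0.1), 1e-3)
  }
})

test_that("configuration geometries have the documented structure", {
  d <- lapply(cfgs, function(cfg) shape_descriptors(cfg$baseline))
  expect_lt(abs(d[[1]]$circularity - 1), 0.01)             # circle
  expect_identical(d[[1]]$focality, 1L)
  expect_identical(d[[5]]$focality, 2L)                    # bifocal
  expect_lt(abs(d[[5]]$circularity - 0.5), 0.01)
  expect_lt(abs(d[[5]]$gini_focality - 2), 0.02)           # equal foci
  expect_lt(d[[6]]$gini_focality, 2 - 0.05)                # unequal foci

  # config 3 is nonconvex: convex hull strictly exceeds the lesion area
  cs3 <- cfgs[[3]]$baseline$contours
  outer_chain <- cs3$chains[[which(!cs3$is_hole)[1]]]
  hull <- outer_chain[grDevices::chull(outer_chain), ]
  hull <- rbind(hull, hull[1, ])
  expect_gt(abs(polygon_area(hull)), d[[3]]$area_mm2 * 1.05)

  # config 7 field has exactly the 1:2 per-focus rates
  v7 <- cfgs[[7]]$field$values
  expect_equal(max(v7) / min(v7), 2, tolerance = 1e-9)

  expect_error(make_config(9), "config_id")
})

test_that("config 8 exhibits interfoci merging within one year", {
  cfg <- cfgs[[8]]
  fb <- shape_descriptors(cfg$baseline)$focality
  sq <- propagate(cfg$baseline, cfg$field, 1, 10)
  ff <- shape_descriptors(sq$states[[11]])$focality
  expect_identical(fb, 2L)
  expect_lt(ff, fb)
})

test_that("sampled baseline lesions are deterministic and in-range", {
  gp <- lesion_gen_params()
  g <- pixel_grid_centered(8, 0.024)
  s1 <- sample_baseline_lesion(gp, g, 17)
  s2 <- sample_baseline_lesion(gp, g, 17)
  expect_identical(s1$mask, s2$mask)

  for (s in 1:8) {
    st <- sample_baseline_lesion(gp, g, 300 + s)
    d <- attr(st, "descriptors")
    expect_gte(d$area_mm2, gp$area_range_mm2[1])
    expect_lte(d$area_mm2, gp$area_range_mm2[2])
    expect_gte(d$focality, gp$focality_range[1])
    expect_lte(d$focality, gp$focality_range[2])
    expect_gte(d$circularity, gp$circularity_range[1])
    expect_lte(d$circularity, gp$circularity_range[2])
    expect_gte(d$gini_focality, 1 - 1e-9)
    expect_lte(d$gini_focality, d$focality + 1e-9)
    # border headroom for follow-up growth
    idx <- which(st$mask, arr.ind = TRUE)
    mpx <- gp$border_margin_mm / g$pixel_size_mm
    expect_gt(min(idx), mpx)
  }
})

test_that("degenerate generator settings force a single compact focus", {
  gp <- lesion_gen_params(area_range_mm2 = c(3, 4), focality_range = c(1, 1),
                          circularity_range = c(0.3, 1),
                          margin_rough_amp = 0, corr_range_mm = c(1.5, 2.5))
  g <- pixel_grid_centered(8, 0.03)
  st <- sample_baseline_lesion(gp, g, 5)
  d <- attr(st, "descriptors")
  expect_identical(d$focality, 1L)
  expect_equal(d$gini_focality, 1)
})

test_that("impossible generator constraints fail loudly", {
  gp <- lesion_gen_params(circularity_range = c(0.999, 1),
                          max_attempts = 5)
  g <- pixel_grid_centered(6, 0.04)
  expect_error(sample_baseline_lesion(gp, g, 1), "attempts")
})
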