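test_that("mm <-> index mapping round-trips to within 1e-9 mm", {
  g <- pixel_grid(137, 95, pixel_size_mm = 0.017, origin_mm = c(-1.3, 0.4))
  set.seed(1)
  xy <- cbind(runif(50, -1.3, 1), runif(50, 0.4, 2))
  back <- index_to_mm(g, mm_to_index(g, xy))
  expect_lt(max(abs(back - xy)), 1e-9)
  expect_equal(diff(grid_x(g))[1], 0.017)
})

test_that("rasterized disks recover analytic area and perimeter to 0.5% at 12 um", {
  g <- small_grid(3, h = 0.012)
  st <- rasterize(shape_disk(c(0, 0), 1), g)
  d <- shape_descriptors(st)
  expect_lt(abs(d$area_mm2 - pi) / pi, 0.005)
  expect_lt(abs(d$perimeter_mm - 2 * pi) / (2 * pi), 0.005)
  expect_lt(abs(d$circularity - 1), 0.01)

  # the 6 mm^2 benchmark disk
  g6 <- small_grid(4, h = 0.012)
  st6 <- rasterize(shape_disk(c(0, 0), sqrt(6 / pi)), g6)
  expect_lt(abs(shape_descriptors(st6)$area_mm2 - 6) / 6, 0.005)
})

test_that("rasterization rejects shapes too close to the border", {
  g <- small_grid(2.2, h = 0.03)
  expect_error(rasterize(shape_disk(c(0, 0), 1.08), g), "border")
})

test_that("union of two disjoint disks has focality 2 and circularity 1/2", {
  st <- rasterize(
    shape_union(shape_disk(c(-0.8, 0), 0.4), shape_disk(c(0.8, 0), 0.4)),
    small_grid(4, h = 0.015)
  )
  d <- shape_descriptors(st)
  expect_identical(d$focality, 2L)
  expect_lt(abs(d$circularity - 0.5), 0.01)          # circ = 1/n
  expect_lt(abs(d$gini_focality - 2), 0.02)          # equal foci
})

test_that("extract_contours handles blocks, circles and donuts", {
  g <- pixel_grid(9, 9, pixel_size_mm = 0.1)
  m <- matrix(FALSE, 9, 9)
  m[4:6, 4:6] <- TRUE
  cs <- extract_contours(m, g)
  expect_length(cs$chains, 1)
  expect_gt(contour_area(cs), 0)

  gd <- small_grid(3, h = 0.012)
  stc <- rasterize(shape_disk(c(0, 0), 1), gd)
  cs2 <- extract_contours(stc$mask, gd)   # from the raw binary mask
  expect_lt(abs(contour_area(cs2) - pi) / pi, 0.005)

  # donut: disk minus concentric disk -> exactly 2 chains, one a hole
  xs <- grid_x(gd)
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  donut <- rr < 1 & rr > 0.5
  cs3 <- extract_contours(donut, gd)
  expect_length(cs3$chains, 2)
  expect_identical(sum(cs3$is_hole), 1L)
  expect_lt(abs(contour_area(cs3) - (pi - pi * 0.25)) / pi, 0.01)
})

test_that("contours regenerated from the mask match stored contours within a pixel", {
  st <- rasterize(
    shape_union(shape_disk(c(-0.7, 0.2), 0.55), shape_disk(c(0.7, -0.2), 0.35)),
    small_grid(4, h = 0.02)
  )
  regen <- extract_contours(st$mask, st$grid)
  expect_lt(contour_hausdorff(st$contours, regen), st$grid$pixel_size_mm)
})

test_that("ellipse circularity matches brute-force arclength quadrature", {
  b <- 0.5
  a <- 2 * b
  st <- rasterize(shape_ellipse(c(0, 0), c(a, b)), small_grid(3, h = 0.012))
  d <- shape_descriptors(st)
  # independent oracle: perimeter by numerical quadrature of the arclength
  per <- stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                          0, 2 * pi, rel.tol = 1e-10)$value
  circ_oracle <- 4 * pi * (pi * a * b) / per^2
  expect_lt(abs(d$circularity - circ_oracle), 0.005)
  expect_lt(abs(circ_oracle - 0.841), 0.005)  # the 2:1 ellipse value
})

test_that("the disk maximizes circularity among equal-area shapes", {
  h <- 0.015
  area <- 1.2
  circ_of <- function(shape) {
    shape_descriptors(rasterize(shape, small_grid(4, h)))$circularity
  }
  c_disk <- circ_of(shape_disk(c(0, 0), sqrt(area / pi)))
  b <- sqrt(area / (2 * pi))
  others <- c(
    circ_of(shape_ellipse(c(0, 0), c(2 * b, b))),
    circ_of(shape_notched_disk(c(0, 0), sqrt(area / (0.84 * pi)))),
    circ_of(shape_union(shape_disk(c(-0.7, 0), sqrt(area / (2 * pi))),
                        shape_disk(c(0.7, 0), sqrt(area / (2 * pi)))))
  )
  expect_true(all(c_disk >= others - 0.01))
  expect_lte(c_disk, 1)
})

test_that("gini_weighted_focality matches its definition and properties", {
  expect_equal(gini_weighted_focality(c(5, 5, 5)), 3)
  expect_equal(gini_weighted_focality(7), 1)

  # brute-force oracle for [2, 1]: G = mean |p_i - p_j| / (2 mu)
  p <- c(2, 1)
  G <- mean(abs(outer(p, p, "-"))) / (2 * mean(p))
  expect_equal(gini_weighted_focality(p), 2 * (1 - G))
  expect_equal(gini_weighted_focality(p), 5 / 3, tolerance = 1e-12)

  # scale invariance and majorization monotonicity
  set.seed(7)
  for (k in 1:5) {
    q <- runif(4, 0.5, 3)
    expect_equal(gini_weighted_focality(q), gini_weighted_focality(13.7 * q),
                 tolerance = 1e-12)
  }
  expect_gt(gini_weighted_focality(c(2, 1)), gini_weighted_focality(c(2.5, 0.5)))
  expect_lte(gini_weighted_focality(c(9, 1, 1)), 3)

  expect_error(gini_weighted_focality(numeric(0)))
  expect_error(gini_weighted_focality(c(1, -1)))
})
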