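#' Benchmark lesion/growth-field configurations
#'
#' Constructs the eight benchmark configurations used for the accuracy
#' sweeps: a hierarchy of baseline geometries and growth fields, every one
#' built to a baseline area of 6 mm^2 and a canonical ground-truth
#' length-type rate of 0.1 mm/year over a 1-year interval.
#'
#' 1. circle, isotropic field;
#' 2. 2:1 ellipse, isotropic field;
#' 3. notched (nonconvex) disk, isotropic field -- growth closes the notch
#'    near its apex (intrafocus merging);
#' 4. circle with an anisotropic field `v ~ 1 + 0.8 cos(2 theta)`;
#' 5. two equal circular foci, isotropic field;
#' 6. two unequal foci (3:1 area split), isotropic field;
#' 7. two equal foci with per-focus constant rates, the top-left focus
#'    growing at half the rate of the bottom-right one;
#' 8. two equal foci separated by a 0.15 mm gap, so isotropic growth at the
#'    canonical rate merges them within 1 year (interfoci merging).
#'
#' Anisotropic fields (4 and 7) are renormalized with
#' [scale_field_to_lambda()] so the canonical rate holds exactly; isotropic
#' fields satisfy it by construction.
#'
#' @param config_id Integer 1-8.
#' @param pixel_size_mm Grid resolution (default 12 micrometres).
#' @param fov_mm Field-of-view side length, mm.
#' @param pad_mm Extra border padding, mm; must cover the maximal planned
#'   growth so propagation is never clipped.
#' @param dt_years Follow-up interval the canonical rate refers to.
#' @param calibrate If `TRUE` (default), renormalize anisotropic fields to
#'   the canonical rate by propagation; isotropic fields never need it.
#' @param n_steps Propagation steps used during renormalization.
#' @return An object of class `ga_config`: list with `config_id`,
#'   `baseline` ([lesion_state()]), `field` ([growth_field()]),
#'   `dt_years`, `lambda_target`, and `description`.
#' @examples
#' cfg <- make_config(1, pixel_size_mm = 0.03)
#' shape_descriptors(cfg$baseline)
#' @export
make_config <- function(config_id, pixel_size_mm = 0.012, fov_mm = 6,
                        pad_mm = 1.0, dt_years = 1, calibrate = TRUE,
                        n_steps = 10) {
  if (!config_id %in% 1:8) stop("config_id must be 1..8", call. = FALSE)
  lambda0 <- 0.1
  grid <- pixel_grid_centered(fov_mm + 2 * pad_mm, pixel_size_mm)

  r_disk <- sqrt(6 / pi)              # unifocal disk, area 6
  b_ell <- sqrt(3 / pi)               # 2:1 ellipse, pi*(2b)*b = 6
  r_half <- sqrt(3 / pi)              # each of two equal 3 mm^2 foci
  # notched disk: disk minus a 60-degree annular-sector wedge of depth
  # 0.8 R; remaining area 0.84 * pi * R^2 = 6
  r_notch <- sqrt(6 / (0.84 * pi))
  # edge-to-edge gap for configs 5-7: these are the nonmerging benchmarks,
  # so the gap must exceed the maximal combined 1-year growth of the two
  # fronts over the swept rates (2 * 0.7 mm)
  sep_wide <- 1.5
  sep_merge <- 0.15                   # gap < 2 * lambda0 * dt: merges

  two_centers <- function(r1, r2, gap) {
    d <- (r1 + r2 + gap) / 2
    u <- d / sqrt(2)
    list(tl = c(-u, u), br = c(u, -u))  # top-left / bottom-right diagonal
  }

  desc <- c(
    "circle, isotropic", "2:1 ellipse, isotropic",
    "notched disk, isotropic (intrafocus merging)",
    "circle, anisotropic cos(2 theta) field",
    "two equal foci, isotropic", "two unequal foci (3:1), isotropic",
    "two equal foci, per-focus rates 1:2",
    "two equal foci, 0.15 mm gap (interfoci merging)"
  )[config_id]

  iso <- function() growth_field(grid, lambda0)

  if (config_id == 1) {
    shape <- shape_disk(c(0, 0), r_disk)
    field <- iso()
  } else if (config_id == 2) {
    shape <- shape_ellipse(c(0, 0), c(2 * b_ell, b_ell))
    field <- iso()
  } else if (config_id == 3) {
    shape <- shape_notched_disk(c(0, 0), r_notch, notch_angle_deg = 60,
                                notch_depth_frac = 0.8, notch_dir_deg = 0)
    field <- iso()
  } else if (config_id == 4) {
    shape <- shape_disk(c(0, 0), r_disk)
    th <- outer(grid_x(grid), grid_y(grid), function(x, y) atan2(y, x))
    field <- growth_field(grid, lambda0 * (1 + 0.8 * cos(2 * th)))
  } else if (config_id == 5) {
    ctr <- two_centers(r_half, r_half, sep_wide)
    shape <- shape_union(shape_disk(ctr$tl, r_half), shape_disk(ctr$br, r_half))
    field <- iso()
  } else if (config_id == 6) {
    r1 <- sqrt(4.5 / pi)
    r2 <- sqrt(1.5 / pi)
    ctr <- two_centers(r1, r2, sep_wide)
    shape <- shape_union(shape_disk(ctr$tl, r1), shape_disk(ctr$br, r2))
    field <- iso()
  } else if (config_id == 7) {
    ctr <- two_centers(r_half, r_half, sep_wide)
    shape <- shape_union(shape_disk(ctr$tl, r_half), shape_disk(ctr$br, r_half))
    # per-focus constant rates: split along the perpendicular bisector of
    # the two centres; top-left at half the bottom-right rate; the 2/3 and
    # 4/3 levels put the initial margin-average near the canonical rate
    v0 <- lambda0 * 2 / 3
    vals <- outer(grid_x(grid), grid_y(grid),
                  function(x, y) ifelse(y - x > 0, v0, 2 * v0))
    field <- growth_field(grid, vals)
  } else {
    ctr <- two_centers(r_half, r_half, sep_merge)
    shape <- shape_union(shape_disk(ctr$tl, r_half), shape_disk(ctr$br, r_half))
    field <- iso()
  }

  baseline <- rasterize(shape, grid)
  if (calibrate && config_id %in% c(4, 7)) {
    field <- scale_field_to_lambda(baseline, field, dt_years, lambda0,
                                   n_steps = n_steps)
  }
  structure(
    list(config_id = as.integer(config_id), baseline = baseline,
         field = field, dt_years = dt_years, lambda_target = lambda0,
         description = desc),
    class = "ga_config"
  )
}

#' @export
print.ga_config <- function(x, ...) {
  cat(sprintf("<ga_config %d> %s\n", x$config_id, x$description))
  print(x$baseline)
  invisible(x)
}

#' Parameters of the random baseline-lesion generator
#'
#' Controls the synthetic multifocal blobs that stand in for clinically
#' observed baseline geometries: smoothed Gaussian noise is thresholded to
#' a target area, cleaned up morphologically (holes filled, sub-resolution
#' foci dropped), and rejection-sampled until the shape descriptors fall in
#' the configured ranges, which emulate a clinical GA cohort's geometry
#' distributions.
#'
#' @param area_range_mm2 Baseline area range, mm^2.
#' @param focality_range Acceptable focus-count range.
#' @param circularity_range Acceptable circularity range.
#' @param corr_range_mm Bounds on the blob texture correlation length, mm.
#'   The scale is tied to the drawn target area (about
#'   `0.5 * sqrt(area)`, clamped to this range) so small lesions are not
#'   shredded into many specks and large ones keep realistic lobedness.
#' @param border_margin_mm Foreground must stay this far from the grid
#'   border (headroom for follow-up growth).
#' @param min_focus_area_mm2 Foci below this area are removed during
#'   cleanup (isolated specks well below clinically reported focus sizes).
#' @param margin_rough_amp,margin_rough_corr_mm Amplitude (relative to the
#'   large-scale texture) and correlation length of a second, fine-scale
#'   noise component that lobulates the margin. Clinical GA margins are
#'   scalloped at sub-millimetre scales, and this roughness is what makes
#'   intrafocus merging during follow-up growth possible; a single smooth
#'   texture scale would produce unrealistically bland margins.
#' @param max_attempts Rejection-sampling cap.
#' @return A `lesion_gen_params` list.
#' @export
lesion_gen_params <- function(area_range_mm2 = c(1, 12),
                              focality_range = c(1, 8),
                              circularity_range = c(0.1, 0.9),
                              corr_range_mm = c(0.45, 1.5),
                              border_margin_mm = 1.0,
                              min_focus_area_mm2 = 0.05,
                              margin_rough_amp = 0.15,
                              margin_rough_corr_mm = 0.15,
                              max_attempts = 100) {
  structure(
    list(area_range_mm2 = area_range_mm2, focality_range = focality_range,
         circularity_range = circularity_range, corr_range_mm = corr_range_mm,
         border_margin_mm = border_margin_mm,
         min_focus_area_mm2 = min_focus_area_mm2,
         margin_rough_amp = margin_rough_amp,
         margin_rough_corr_mm = margin_rough_corr_mm,
         max_attempts = max_attempts),
    class = "lesion_gen_params"
  )
}

#' Sample a random clinical-like baseline lesion
#'
#' @param gen_params A [lesion_gen_params()].
#' @param grid A [pixel_grid()].
#' @param seed Integer seed; the lesion is deterministic given
#'   `(gen_params, grid, seed)`.
#' @return A [lesion_state()] with attribute `descriptors` (the accepted
#'   shape descriptors).
#' @export
sample_baseline_lesion <- function(gen_params, grid, seed) {
  stopifnot(inherits(gen_params, "lesion_gen_params"), inherits(grid, "pixel_grid"))
  withr::with_seed(as.integer(seed), sample_lesion_impl(gen_params, grid))
}

sample_lesion_impl <- function(gp, grid) {
  h <- grid$pixel_size_mm
  nx <- grid$width_px
  ny <- grid$height_px
  total_area <- nx * ny * h^2
  # smooth penalty pushing foreground away from the border
  margin_px <- gp$border_margin_mm / h
  di <- pmin(seq_len(nx) - 1, nx - seq_len(nx))
  dj <- pmin(seq_len(ny) - 1, ny - seq_len(ny))
  border_pen <- outer(di, dj, function(a, b) {
    d <- pmin(a, b) / (1.8 * margin_px)
    8 * pmax(1 - d, 0)^2
  })
  near_border <- outer(di, dj, function(a, b) pmin(a, b) < ceiling(margin_px))
  for (attempt in seq_len(gp$max_attempts)) {
    target_area <- stats::runif(1, gp$area_range_mm2[1], gp$area_range_mm2[2])
    # texture scale tied to lesion size, clamped to the configured range
    corr <- min(max(0.5 * sqrt(target_area), gp$corr_range_mm[1]),
                gp$corr_range_mm[2])
    z <- grf_sample(grid, corr)
    if (gp$margin_rough_amp > 0) {
      zr <- grf_sample(grid, max(gp$margin_rough_corr_mm, 2 * h))
      z <- (z + gp$margin_rough_amp * zr) / sqrt(1 + gp$margin_rough_amp^2)
    }
    z <- z - border_pen
    thr <- stats::quantile(z, 1 - target_area / total_area, names = FALSE)
    lev <- z - thr
    mask <- lev > 0
    if (!any(mask)) next
    # fill enclosed holes (4-connected background not touching the border)
    lev <- fill_holes_level(lev, mask)
    # drop specks below the minimum focus area (8-connected)
    lev <- drop_small_foci_level(lev, lev > 0,
                                 min_px = max(4, gp$min_focus_area_mm2 / h^2))
    # discard foci encroaching on the border margin (no headroom for growth)
    lev <- drop_border_foci_level(lev, lev > 0, near_border)
    mask <- lev > 0
    if (!any(mask)) next
    # cheap pre-checks before subpixel contouring
    n_lab <- max(label_components_cpp(mask, TRUE))
    if (n_lab < gp$focality_range[1] || n_lab > gp$focality_range[2]) next
    cs <- contours_from_values(lev, grid, level = 0)
    if (length(cs$chains) == 0) next
    d <- shape_descriptors(cs, pixel_size_mm = h)
    ok <- d$area_mm2 >= gp$area_range_mm2[1] &&
      d$area_mm2 <= gp$area_range_mm2[2] &&
      d$focality >= gp$focality_range[1] &&
      d$focality <= gp$focality_range[2] &&
      d$circularity >= gp$circularity_range[1] &&
      d$circularity <= gp$circularity_range[2]
    if (!ok) next
    st <- lesion_state(grid, mask, cs, time_years = 0)
    attr(st, "descriptors") <- d
    return(st)
  }
  stop("failed to sample an acceptable lesion in ", gp$max_attempts,
       " attempts", call. = FALSE)
}

# set the level function positive inside enclosed holes so they disappear
# from the zero level set while staying continuous
fill_holes_level <- function(lev, mask) {
  bg <- label_components_cpp(!mask, FALSE)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  hole <- bg > 0 & !(bg %in% border_labels)
  if (any(hole)) lev[hole] <- abs(lev[hole])
  lev
}

# flip the level function negative on foci touching the border ring
drop_border_foci_level <- function(lev, mask, near_border) {
  lab <- label_components_cpp(mask, TRUE)
  if (max(lab) == 0) return(lev)
  bad <- unique(lab[near_border & lab > 0])
  if (length(bad)) {
    kill <- lab %in% bad
    lev[kill] <- -abs(lev[kill])
  }
  lev
}

# flip the level function negative on foci smaller than min_px pixels
drop_small_foci_level <- function(lev, mask, min_px = 4) {
  lab <- label_components_cpp(mask, TRUE)
  if (max(lab) == 0) return(lev)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_px)
  if (length(small)) {
    kill <- lab %in% small
    lev[kill] <- -abs(lev[kill])
  }
  lev
}
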