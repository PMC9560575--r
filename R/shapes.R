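#' Analytic shape specifications
#'
#' Shapes are described by a continuous level function `f(x, y)` that is
#' positive inside the shape, negative outside, and zero exactly on the
#' boundary. Rasterization marks a pixel as foreground iff its centre lies
#' inside the shape, and subpixel contours are extracted from the level
#' function itself (not from the binary mask), so the measured area and
#' perimeter converge quadratically with pixel size.
#'
#' @param center Length-2 mm coordinate of the shape centre.
#' @param radius Disk radius in mm.
#' @return A `shape_spec` object.
#' @name shape_spec
NULL

new_shape <- function(type, ...) {
  structure(list(type = type, ...), class = "shape_spec")
}

#' @rdname shape_spec
#' @export
shape_disk <- function(center, radius) {
  stopifnot(radius > 0)
  new_shape("disk", center = center, radius = radius)
}

#' @rdname shape_spec
#' @param semi_axes Length-2 vector `(a, b)` of ellipse semi-axes in mm.
#' @param angle_deg Rotation of the first axis from +x, degrees.
#' @export
shape_ellipse <- function(center, semi_axes, angle_deg = 0) {
  stopifnot(length(semi_axes) == 2, all(semi_axes > 0))
  new_shape("ellipse", center = center, semi_axes = semi_axes,
            angle_deg = angle_deg)
}

#' @rdname shape_spec
#' @param notch_angle_deg Angular width of the removed wedge, degrees.
#' @param notch_depth_frac Notch depth as a fraction of the disk radius;
#'   the wedge spans radii `(1 - notch_depth_frac) * radius` to the boundary.
#' @param notch_dir_deg Direction of the notch centreline, degrees from +x.
#' @export
shape_notched_disk <- function(center, radius, notch_angle_deg = 60,
                               notch_depth_frac = 0.8, notch_dir_deg = 0) {
  stopifnot(radius > 0, notch_angle_deg > 0, notch_angle_deg < 180,
            notch_depth_frac > 0, notch_depth_frac < 1)
  new_shape("notched_disk", center = center, radius = radius,
            notch_angle_deg = notch_angle_deg,
            notch_depth_frac = notch_depth_frac,
            notch_dir_deg = notch_dir_deg)
}

#' @rdname shape_spec
#' @param ... For `shape_union()`: shapes to combine.
#' @export
shape_union <- function(...) {
  shapes <- list(...)
  if (length(shapes) == 1 && is.list(shapes[[1]]) &&
      !inherits(shapes[[1]], "shape_spec")) {
    shapes <- shapes[[1]]
  }
  stopifnot(length(shapes) >= 1,
            all(vapply(shapes, inherits, logical(1), "shape_spec")))
  new_shape("union", shapes = shapes)
}

#' @rdname shape_spec
#' @param vertices Two-column matrix of polygon vertices in mm (closed or
#'   open; closed automatically).
#' @export
shape_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  if (any(vertices[1, ] != vertices[nrow(vertices), ])) {
    vertices <- rbind(vertices, vertices[1, ])
  }
  new_shape("polygon", vertices = vertices)
}

# evaluate the level function of `shape` at coordinates (x, y); positive
# inside. For polygons the level is the even-odd inside indicator scaled to
# +-1 (contours for polygons are refined through the signed mask distance).
shape_level <- function(shape, x, y) {
  switch(shape$type,
    disk = shape$radius - sqrt((x - shape$center[1])^2 + (y - shape$center[2])^2),
    ellipse = {
      th <- shape$angle_deg * pi / 180
      dx <- x - shape$center[1]
      dy <- y - shape$center[2]
      u <- cos(th) * dx + sin(th) * dy
      w <- -sin(th) * dx + cos(th) * dy
      rho <- sqrt((u / shape$semi_axes[1])^2 + (w / shape$semi_axes[2])^2)
      min(shape$semi_axes) * (1 - rho)
    },
    notched_disk = {
      dx <- x - shape$center[1]
      dy <- y - shape$center[2]
      r <- sqrt(dx^2 + dy^2)
      f_disk <- shape$radius - r
      # wedge: annular sector of half-width w2 about notch_dir, radii
      # r_in..outward; positive inside the wedge
      w2 <- shape$notch_angle_deg / 2 * pi / 180
      r_in <- (1 - shape$notch_depth_frac) * shape$radius
      dth <- atan2(dy, dx) - shape$notch_dir_deg * pi / 180
      dth <- atan2(sin(dth), cos(dth))  # wrap to (-pi, pi]
      f_ang <- (w2 - abs(dth)) * pmax(r, 1e-9)
      f_wedge <- pmin(f_ang, r - r_in)
      pmin(f_disk, -f_wedge)
    },
    union = {
      vals <- lapply(shape$shapes, shape_level, x = x, y = y)
      Reduce(pmax, vals)
    },
    polygon = {
      inside <- points_in_chains_cpp(x, y, list(shape$vertices))
      ifelse(inside, 1, -1)
    },
    stop("unknown shape type: ", shape$type, call. = FALSE)
  )
}

#' Lesion state: binary mask plus subpixel contours at one time point
#'
#' @param grid A [pixel_grid()].
#' @param mask Logical matrix on `grid` with at least one foreground pixel.
#' @param contours A [contour_set()]; if `NULL`, contours are extracted
#'   from the mask via its signed distance function.
#' @param time_years Time stamp of the state.
#' @return An object of class `lesion_state`.
#' @export
lesion_state <- function(grid, mask, contours = NULL, time_years = 0) {
  m <- mask_logical(mask)
  stopifnot(inherits(grid, "pixel_grid"),
            nrow(m) == grid$width_px, ncol(m) == grid$height_px)
  if (!any(m)) stop("mask has no foreground pixels", call. = FALSE)
  if (is.null(contours)) contours <- extract_contours(m, grid)
  structure(
    list(grid = grid, mask = m, contours = contours,
         time_years = as.numeric(time_years)),
    class = "lesion_state"
  )
}

#' @export
print.lesion_state <- function(x, ...) {
  d <- shape_descriptors(x)
  cat(sprintf(
    "<lesion_state> t = %g yr: area %.4g mm^2, perimeter %.4g mm, circularity %.3f, focality %d\n",
    x$time_years, d$area_mm2, d$perimeter_mm, d$circularity, d$focality
  ))
  invisible(x)
}

#' Rasterize an analytic shape onto a physical grid
#'
#' A pixel is foreground iff its centre lies inside the shape; contours are
#' extracted at subpixel precision from the shape's level function. The
#' shape must keep a margin of at least 5 pixels from the grid border so
#' subsequent front propagation is not clipped.
#'
#' @param shape A `shape_spec` (see [shape_disk()] and friends).
#' @param grid A [pixel_grid()].
#' @param time_years Time stamp for the resulting state.
#' @return A [lesion_state()].
#' @examples
#' g <- pixel_grid_centered(4, pixel_size_mm = 0.02)
#' st <- rasterize(shape_disk(c(0, 0), 1), g)
#' shape_descriptors(st)
#' @export
rasterize <- function(shape, grid, time_years = 0) {
  stopifnot(inherits(shape, "shape_spec"), inherits(grid, "pixel_grid"))
  xs <- grid_x(grid)
  ys <- grid_y(grid)
  lev <- outer(xs, ys, function(x, y) shape_level(shape, x, y))
  mask <- lev > 0
  if (!any(mask)) stop("shape does not cover any pixel centre", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  margin <- 5L
  if (min(idx[, 1]) <= margin || max(idx[, 1]) > grid$width_px - margin ||
      min(idx[, 2]) <= margin || max(idx[, 2]) > grid$height_px - margin) {
    stop("shape lies within 5 pixels of the grid border; enlarge the grid",
         call. = FALSE)
  }
  contours <- if (shape$type == "polygon") {
    extract_contours(mask, grid)
  } else {
    contours_from_values(lev, grid, level = 0)
  }
  lesion_state(grid, mask, contours, time_years)
}
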