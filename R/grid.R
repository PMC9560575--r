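#' Physical pixel grid
#'
#' A `pixel_grid` describes the physical raster geometry on which lesion
#' masks and growth fields live: a uniform grid of square pixels of side
#' `pixel_size_mm`, with `origin_mm` giving the mm coordinate of the centre
#' of pixel `(1, 1)`. Matrices on a grid are indexed `[i, j]` with `i`
#' running along x (`width_px` rows) and `j` along y (`height_px` columns),
#' which matches the convention of [grDevices::contourLines()].
#'
#' @param width_px,height_px Positive integers, grid size in pixels.
#' @param pixel_size_mm Positive pixel side length in mm. The default,
#'   0.012 mm (12 micrometres), is the resolution used for the benchmark
#'   configuration simulations.
#' @param origin_mm Length-2 numeric, mm coordinate of the centre of the
#'   first pixel.
#' @return An object of class `pixel_grid`.
#' @examples
#' g <- pixel_grid(100, 100, pixel_size_mm = 0.05)
#' range(grid_x(g))
#' @export
pixel_grid <- function(width_px, height_px, pixel_size_mm = 0.012,
                       origin_mm = c(0, 0)) {
  stopifnot(
    is.numeric(pixel_size_mm), length(pixel_size_mm) == 1, pixel_size_mm > 0,
    width_px >= 1, height_px >= 1, length(origin_mm) == 2,
    all(is.finite(origin_mm))
  )
  structure(
    list(
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      pixel_size_mm = as.numeric(pixel_size_mm),
      origin_mm = as.numeric(origin_mm)
    ),
    class = "pixel_grid"
  )
}

#' Square grid centred on the origin
#'
#' Convenience constructor for a square field of view of physical extent
#' `extent_mm`, centred at (0, 0).
#'
#' @param extent_mm Physical side length of the field of view in mm.
#' @inheritParams pixel_grid
#' @return A `pixel_grid`.
#' @export
pixel_grid_centered <- function(extent_mm, pixel_size_mm = 0.012) {
  n <- max(2L, as.integer(round(extent_mm / pixel_size_mm)))
  half <- (n - 1) / 2 * pixel_size_mm
  pixel_grid(n, n, pixel_size_mm, origin_mm = c(-half, -half))
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf(
    "<pixel_grid> %d x %d px @ %g mm (%.3g x %.3g mm)\n",
    x$width_px, x$height_px, x$pixel_size_mm,
    x$width_px * x$pixel_size_mm, x$height_px * x$pixel_size_mm
  ))
  invisible(x)
}

#' Pixel-centre coordinates of a grid
#'
#' @param grid A [pixel_grid()].
#' @return Numeric vector of pixel-centre x (or y) coordinates in mm.
#' @export
grid_x <- function(grid) {
  grid$origin_mm[1] + (seq_len(grid$width_px) - 1) * grid$pixel_size_mm
}

#' @rdname grid_x
#' @export
grid_y <- function(grid) {
  grid$origin_mm[2] + (seq_len(grid$height_px) - 1) * grid$pixel_size_mm
}

#' Convert between mm coordinates and (fractional) pixel indices
#'
#' Index 1 corresponds to `origin_mm`; indices are continuous, so the
#' round trip `index_to_mm(mm_to_index(p))` is the identity.
#'
#' @param grid A [pixel_grid()].
#' @param xy Two-column matrix (or length-2 vector) of mm coordinates or
#'   fractional indices.
#' @return Two-column matrix.
#' @export
mm_to_index <- function(grid, xy) {
  xy <- rbind_xy(xy)
  cbind(
    (xy[, 1] - grid$origin_mm[1]) / grid$pixel_size_mm + 1,
    (xy[, 2] - grid$origin_mm[2]) / grid$pixel_size_mm + 1
  )
}

#' @rdname mm_to_index
#' @export
index_to_mm <- function(grid, xy) {
  xy <- rbind_xy(xy)
  cbind(
    grid$origin_mm[1] + (xy[, 1] - 1) * grid$pixel_size_mm,
    grid$origin_mm[2] + (xy[, 2] - 1) * grid$pixel_size_mm
  )
}

rbind_xy <- function(xy) {
  if (is.null(dim(xy))) matrix(xy, ncol = 2) else as.matrix(xy)
}

grids_compatible <- function(a, b, tol = 1e-9) {
  a$width_px == b$width_px && a$height_px == b$height_px &&
    abs(a$pixel_size_mm - b$pixel_size_mm) < tol &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

#' Bilinear interpolation of a raster at mm coordinates
#'
#' Values outside the grid are clamped to the nearest edge.
#'
#' @param values Matrix on `grid` (`width_px` x `height_px`).
#' @param grid A [pixel_grid()].
#' @param x,y Numeric vectors of mm coordinates.
#' @return Numeric vector of interpolated values.
#' @export
bilinear_at <- function(values, grid, x, y) {
  h <- grid$pixel_size_mm
  fx <- (x - grid$origin_mm[1]) / h
  fy <- (y - grid$origin_mm[2]) / h
  fx <- pmin(pmax(fx, 0), grid$width_px - 1)
  fy <- pmin(pmax(fy, 0), grid$height_px - 1)
  i0 <- pmin(floor(fx), grid$width_px - 2)
  j0 <- pmin(floor(fy), grid$height_px - 2)
  wx <- fx - i0
  wy <- fy - j0
  i0 <- i0 + 1  # 1-based
  j0 <- j0 + 1
  n <- grid$width_px
  idx <- function(i, j) i + (j - 1) * n
  v00 <- values[idx(i0, j0)]
  v10 <- values[idx(i0 + 1, j0)]
  v01 <- values[idx(i0, j0 + 1)]
  v11 <- values[idx(i0 + 1, j0 + 1)]
  v00 * (1 - wx) * (1 - wy) + v10 * wx * (1 - wy) +
    v01 * (1 - wx) * wy + v11 * wx * wy
}
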