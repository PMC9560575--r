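#' Static shape descriptors of a lesion
#'
#' Computes area (shoelace, subpixel contours), perimeter (contour
#' arclength), circularity `4*pi*A/P^2` (clipped to `[0, 1]`), focality
#' (number of lesion foci, i.e. outer contour chains), and Gini-weighted
#' focality. Foci smaller than `min_focus_px` pixels are treated as
#' sub-resolution artifacts and discarded before computation.
#'
#' @param x A [lesion_state()] or [contour_set()].
#' @param pixel_size_mm Pixel size, needed only when `x` is a contour set
#'   (for the minimum focus area); taken from the grid otherwise.
#' @param min_focus_px Minimum focus area in pixels (default 4).
#' @return A one-row [tibble::tibble()] with columns `area_mm2`,
#'   `perimeter_mm`, `circularity`, `focality`, `gini_focality`.
#' @examples
#' g <- pixel_grid_centered(4, 0.02)
#' shape_descriptors(rasterize(shape_disk(c(0, 0), 1), g))
#' @export
shape_descriptors <- function(x, pixel_size_mm = NULL, min_focus_px = 4) {
  if (inherits(x, "lesion_state")) {
    cs <- x$contours
    pixel_size_mm <- x$grid$pixel_size_mm
  } else if (inherits(x, "contour_set")) {
    cs <- x
    if (is.null(pixel_size_mm)) pixel_size_mm <- 0
  } else {
    stop("x must be a lesion_state or contour_set", call. = FALSE)
  }
  cs <- drop_small_foci(cs, min_area = min_focus_px * pixel_size_mm^2)
  n_foci <- sum(!cs$is_hole)
  if (n_foci == 0) stop("no foci left after sub-resolution filtering", call. = FALSE)
  area <- contour_area(cs)
  per <- contour_perimeter(cs)
  circ <- if (per > 0) min(max(4 * pi * area / per^2, 0), 1) else 1
  per_focus <- focus_perimeters(cs)
  tibble::tibble(
    area_mm2 = area,
    perimeter_mm = per,
    circularity = circ,
    focality = n_foci,
    gini_focality = gini_weighted_focality(per_focus)
  )
}

# total boundary length per focus (outer chain plus its holes)
focus_perimeters <- function(cs) {
  n_foci <- sum(!cs$is_hole)
  vapply(seq_len(n_foci), function(f) sum(cs$length[cs$focus == f]), numeric(1))
}

drop_small_foci <- function(cs, min_area) {
  if (min_area <= 0 || length(cs$chains) == 0) return(cs)
  outer_idx <- which(!cs$is_hole)
  small <- outer_idx[cs$area[outer_idx] < min_area]
  if (length(small) == 0 || length(small) == length(outer_idx)) return(cs)
  small_focus <- match(small, outer_idx)
  keep <- !(cs$focus %in% small_focus)
  contour_set(cs$chains[keep])
}

#' Gini-weighted focality
#'
#' An effective focus count that discounts unequal foci: `n * (1 - G)`,
#' where `G` is the Gini coefficient of the per-focus perimeters,
#' `G = sum_{i,j} |p_i - p_j| / (2 n^2 mean(p))`. It equals the number of
#' foci when all foci have equal perimeters, is strictly smaller for
#' unequal perimeters, and is invariant to rescaling all perimeters.
#'
#' @param foci_perimeters Numeric vector of positive per-focus perimeters.
#' @return A scalar in `[1, length(foci_perimeters)]`.
#' @examples
#' gini_weighted_focality(c(1, 1, 1))  # 3
#' gini_weighted_focality(c(2, 1))     # 5/3
#' @export
gini_weighted_focality <- function(foci_perimeters) {
  p <- as.numeric(foci_perimeters)
  if (length(p) == 0) stop("empty perimeter list", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("foci perimeters must be positive", call. = FALSE)
  }
  n <- length(p)
  if (n == 1) return(1)
  g <- sum(abs(outer(p, p, "-"))) / (2 * n^2 * mean(p))
  n * (1 - g)
}
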