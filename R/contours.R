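#' Closed subpixel contour set
#'
#' A `contour_set` holds closed polygon chains in mm coordinates together
#' with their orientation (outer boundaries counter-clockwise, holes
#' clockwise), signed areas, arclengths, and a grouping of hole chains with
#' the focus (outer chain) that contains them.
#'
#' @param chains List of two-column matrices of mm coordinates. Chains are
#'   closed automatically (the first vertex is appended if missing).
#' @return An object of class `contour_set` with elements `chains`,
#'   `is_hole`, `area` (unsigned, per chain), `length`, and `focus`
#'   (index of the owning outer chain, by position among outer chains).
#' @export
contour_set <- function(chains) {
  stopifnot(is.list(chains))
  chains <- lapply(chains, function(ch) {
    ch <- as.matrix(ch)
    stopifnot(ncol(ch) == 2, nrow(ch) >= 3)
    if (any(ch[1, ] != ch[nrow(ch), ])) ch <- rbind(ch, ch[1, ])
    unname(ch)
  })
  k <- length(chains)
  if (k == 0) {
    return(structure(
      list(chains = list(), is_hole = logical(0), area = numeric(0),
           length = numeric(0), focus = integer(0)),
      class = "contour_set"
    ))
  }
  sgn_area <- vapply(chains, polygon_area, numeric(1))
  len <- vapply(chains, chain_length, numeric(1))
  # containment parity: a chain inside an odd number of other chains is a hole
  depth <- integer(k)
  if (k > 1) {
    for (a in seq_len(k)) {
      p <- chains[[a]][1, ]
      for (b in seq_len(k)) {
        if (a == b) next
        if (points_in_chains_cpp(p[1], p[2], chains[b])) {
          depth[a] <- depth[a] + 1L
        }
      }
    }
  }
  is_hole <- depth %% 2L == 1L
  # orientation convention: outer CCW (positive signed area), hole CW
  for (a in seq_len(k)) {
    want_pos <- !is_hole[a]
    if ((sgn_area[a] > 0) != want_pos) {
      chains[[a]] <- chains[[a]][rev(seq_len(nrow(chains[[a]]))), , drop = FALSE]
      sgn_area[a] <- -sgn_area[a]
    }
  }
  # assign each hole to the smallest outer chain containing it
  outer_idx <- which(!is_hole)
  focus <- integer(k)
  focus[outer_idx] <- seq_along(outer_idx)
  for (a in which(is_hole)) {
    p <- chains[[a]][1, ]
    best <- NA_integer_
    best_area <- Inf
    for (oi in seq_along(outer_idx)) {
      b <- outer_idx[oi]
      if (points_in_chains_cpp(p[1], p[2], chains[b]) &&
          abs(sgn_area[b]) < best_area) {
        best <- oi
        best_area <- abs(sgn_area[b])
      }
    }
    focus[a] <- if (is.na(best)) 0L else best
  }
  structure(
    list(chains = chains, is_hole = is_hole, area = abs(sgn_area),
         length = len, focus = focus),
    class = "contour_set"
  )
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf(
    "<contour_set> %d chain(s): %d outer, %d hole(s); area %.4g mm^2, perimeter %.4g mm\n",
    length(x$chains), sum(!x$is_hole), sum(x$is_hole),
    contour_area(x), contour_perimeter(x)
  ))
  invisible(x)
}

#' Shoelace signed area of a closed chain
#'
#' Positive for counter-clockwise orientation.
#'
#' @param ch Two-column matrix, closed (first row equals last row).
#' @return Signed area.
#' @export
polygon_area <- function(ch) {
  x <- ch[, 1]
  y <- ch[, 2]
  n <- length(x)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Arclength of a polygon chain
#'
#' @param ch Two-column matrix of vertices.
#' @return Total arclength.
#' @export
chain_length <- function(ch) {
  sum(sqrt(diff(ch[, 1])^2 + diff(ch[, 2])^2))
}

#' Total enclosed area of a contour set (outer minus holes)
#'
#' @param cs A [contour_set()].
#' @return Area in mm^2.
#' @export
contour_area <- function(cs) {
  sum(cs$area[!cs$is_hole]) - sum(cs$area[cs$is_hole])
}

#' Total boundary length of a contour set
#'
#' @param cs A [contour_set()].
#' @return Perimeter in mm (all chains, holes included).
#' @export
contour_perimeter <- function(cs) {
  sum(cs$length)
}

#' Subpixel iso-contours of a scalar raster
#'
#' Extracts closed marching-squares contours of `values` at `level`, with
#' vertices linearly interpolated between pixel centres (subpixel
#' precision). Non-finite values are capped so the contour topology near
#' the level crossing is unaffected.
#'
#' @param values Matrix on `grid`.
#' @param grid A [pixel_grid()].
#' @param level Contour level.
#' @return A [contour_set()].
#' @export
contours_from_values <- function(values, grid, level) {
  v <- values
  if (any(!is.finite(v))) {
    hi <- suppressWarnings(max(v[is.finite(v)]))
    if (!is.finite(hi)) hi <- level + 1
    v[!is.finite(v) & v > 0] <- hi + abs(level) + 1e6
    v[!is.finite(v) & v < 0] <- -(abs(level) + 1e6)
    v[is.na(values)] <- -(abs(level) + 1e6)
  }
  cl <- grDevices::contourLines(grid_x(grid), grid_y(grid), v, levels = level)
  contour_set(lapply(cl, function(cc) cbind(cc$x, cc$y)))
}

#' Subpixel contours of a binary mask
#'
#' For a raw binary mask (with no underlying smooth function available) the
#' boundary is taken as the zero level of the signed Euclidean distance
#' function of the mask, which places the margin halfway between foreground
#' and background pixel centres with subpixel interpolation.
#'
#' @param mask Logical (or 0/1) matrix on `grid`.
#' @param grid A [pixel_grid()].
#' @return A [contour_set()].
#' @export
extract_contours <- function(mask, grid) {
  m <- mask_logical(mask)
  if (!any(m)) stop("mask has no foreground pixels", call. = FALSE)
  phi <- signed_distance(m) * grid$pixel_size_mm
  contours_from_values(-phi, grid, level = 0)
}

# signed distance in pixel units: negative inside, positive outside,
# zero level halfway between foreground and background pixel centres
signed_distance <- function(mask) {
  d_to_fg <- edt_cpp(mask)      # distance to nearest foreground pixel
  d_to_bg <- edt_cpp(!mask)     # distance to nearest background pixel
  out <- ifelse(mask, -(d_to_bg - 0.5), d_to_fg - 0.5)
  if (!any(!mask)) out[] <- -d_to_fg  # degenerate: all foreground
  out
}

mask_logical <- function(mask) {
  if (is.logical(mask)) mask else mask > 0.5
}

#' Hausdorff distance between two binary masks
#'
#' Symmetric Hausdorff distance between the foreground pixel sets of two
#' masks on the same grid, in mm.
#'
#' @param a,b Logical matrices of equal dimension.
#' @param pixel_size_mm Pixel size in mm.
#' @return Distance in mm (0 if the masks are identical; Inf if exactly one
#'   is empty).
#' @export
hausdorff_mask <- function(a, b, pixel_size_mm) {
  a <- mask_logical(a)
  b <- mask_logical(b)
  if (identical(a, b)) return(0)
  if (!any(a) || !any(b)) return(Inf)
  da <- edt_cpp(a)
  db <- edt_cpp(b)
  d1 <- if (any(a & !b)) max(db[a & !b]) else 0
  d2 <- if (any(b & !a)) max(da[b & !a]) else 0
  max(d1, d2) * pixel_size_mm
}
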