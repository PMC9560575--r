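# small shared constructors; expensive fixtures are built once at the top
# of the files that need them

small_grid <- function(extent_mm = 4, h = 0.03) {
  pixel_grid_centered(extent_mm, pixel_size_mm = h)
}

disk_state <- function(r = 1, h = 0.03, extent_mm = 4, center = c(0, 0)) {
  rasterize(shape_disk(center, r), small_grid(extent_mm, h))
}

# symmetric vertex-to-polyline Hausdorff distance between two contour sets
contour_hausdorff <- function(a, b) {
  pts <- function(cs) do.call(rbind, cs$chains)
  seg_min_dist <- function(p, ch) {
    # distance from points p (n x 2) to polyline ch
    d <- rep(Inf, nrow(p))
    for (s in seq_len(nrow(ch) - 1)) {
      dx <- ch[s + 1, 1] - ch[s, 1]
      dy <- ch[s + 1, 2] - ch[s, 2]
      L2 <- dx^2 + dy^2
      t <- if (L2 > 0) pmin(pmax(((p[, 1] - ch[s, 1]) * dx + (p[, 2] - ch[s, 2]) * dy) / L2, 0), 1) else 0
      d <- pmin(d, sqrt((ch[s, 1] + t * dx - p[, 1])^2 + (ch[s, 2] + t * dy - p[, 2])^2))
    }
    d
  }
  one_way <- function(x, y) {
    p <- pts(x)
    d <- rep(Inf, nrow(p))
    for (ch in y$chains) d <- pmin(d, seg_min_dist(p, ch))
    max(d)
  }
  max(one_way(a, b), one_way(b, a))
}
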