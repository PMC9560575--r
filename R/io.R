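#' Read and write lesion masks and growth fields
#'
#' Masks are stored as single-channel PNG or TIFF images (0 = background,
#' 255/1 = foreground) with a YAML sidecar declaring the physical grid
#' (`pixel_size_mm`, `origin_mm`); growth fields as single-channel
#' floating-point TIFF (mm/year) with the same sidecar. Image rows run
#' top-to-bottom, so row 1 holds the largest y coordinate.
#'
#' @param state A [lesion_state()].
#' @param path Image file path (`.png` or `.tif`/`.tiff`); the sidecar is
#'   written next to it as `<path>.yml`.
#' @return `path`, invisibly (writers); a [lesion_state()] or
#'   [growth_field()] (readers).
#' @name lesion_io
NULL

sidecar_path <- function(path) paste0(path, ".yml")

write_sidecar <- function(grid, path, extra = list()) {
  yaml::write_yaml(c(list(
    pixel_size_mm = grid$pixel_size_mm,
    width_px = grid$width_px,
    height_px = grid$height_px,
    origin_mm = as.numeric(grid$origin_mm)
  ), extra), sidecar_path(path))
}

read_sidecar <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  list(
    grid = pixel_grid(meta$width_px, meta$height_px, meta$pixel_size_mm,
                      as.numeric(meta$origin_mm)),
    meta = meta
  )
}

# our matrices are [i = x, j = y] with y increasing; image arrays are
# [row = y downwards, col = x]
matrix_to_image <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
image_to_matrix <- function(img) t(img[rev(seq_len(nrow(img))), , drop = FALSE])

#' @rdname lesion_io
#' @export
write_mask <- function(state, path) {
  stopifnot(inherits(state, "lesion_state"))
  img <- matrix_to_image(ifelse(state$mask, 1, 0))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path)
  } else {
    stop("unsupported mask format: .", ext, call. = FALSE)
  }
  write_sidecar(state$grid, path, list(time_years = state$time_years))
  invisible(path)
}

#' @rdname lesion_io
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported mask format: .", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  sc <- read_sidecar(path)
  mask <- image_to_matrix(img) > 0.5
  time_years <- if (!is.null(sc$meta$time_years)) sc$meta$time_years else 0
  lesion_state(sc$grid, mask, time_years = time_years)
}

#' @rdname lesion_io
#' @param field A [growth_field()].
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "growth_field"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff")) {
    stop("growth fields are written as floating-point TIFF", call. = FALSE)
  }
  tiff::writeTIFF(matrix_to_image(field$values), path,
                  bits.per.sample = 32, reduce = FALSE)
  write_sidecar(field$grid, path)
  invisible(path)
}

#' @rdname lesion_io
#' @export
read_field <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  sc <- read_sidecar(path)
  growth_field(sc$grid, image_to_matrix(img))
}

#' Export contours as GeoJSON or WKT
#'
#' Contours are grouped per focus into polygons (outer ring plus holes) and
#' written as a GeoJSON MultiPolygon (mm coordinates) or a WKT
#' `MULTIPOLYGON` string.
#'
#' @param cs A [contour_set()] (or a [lesion_state()], whose contours are
#'   used).
#' @param path Output file for GeoJSON.
#' @return `path` invisibly; `contours_to_wkt()` returns a string;
#'   `read_geojson_contours()` returns a [contour_set()].
#' @export
contours_to_geojson <- function(cs, path) {
  polys <- contour_polygons(cs)
  gj <- list(
    type = "Feature",
    geometry = list(
      type = "MultiPolygon",
      coordinates = lapply(polys, function(rings) {
        lapply(rings, function(ch) {
          lapply(seq_len(nrow(ch)), function(i) c(ch[i, 1], ch[i, 2]))
        })
      })
    ),
    properties = list(units = "mm")
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname contours_to_geojson
#' @export
read_geojson_contours <- function(path) {
  gj <- jsonlite::read_json(path)
  coords <- gj$geometry$coordinates
  chains <- list()
  for (rings in coords) {
    for (ring in rings) {
      chains[[length(chains) + 1]] <-
        do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    }
  }
  contour_set(chains)
}

#' @rdname contours_to_geojson
#' @export
contours_to_wkt <- function(cs) {
  polys <- contour_polygons(cs)
  poly_txt <- vapply(polys, function(rings) {
    ring_txt <- vapply(rings, function(ch) {
      paste0("(", paste(sprintf("%.9g %.9g", ch[, 1], ch[, 2]), collapse = ", "), ")")
    }, character(1))
    paste0("(", paste(ring_txt, collapse = ", "), ")")
  }, character(1))
  paste0("MULTIPOLYGON (", paste(poly_txt, collapse = ", "), ")")
}

# list of polygons: each element = list(outer ring, hole rings...)
contour_polygons <- function(cs) {
  if (inherits(cs, "lesion_state")) cs <- cs$contours
  stopifnot(inherits(cs, "contour_set"))
  outer_idx <- which(!cs$is_hole)
  lapply(seq_along(outer_idx), function(f) {
    rings <- c(outer_idx[f], which(cs$is_hole & cs$focus == f))
    cs$chains[rings]
  })
}

#' Export a margin sequence to a directory
#'
#' Writes one mask PNG and one GeoJSON per saved time step plus a manifest
#' CSV of per-step descriptors (time, area, perimeter, circularity,
#' focality).
#'
#' @param seq A [margin_sequence()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
export_margin_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "margin_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(seq$states)) {
    st <- seq$states[[k]]
    stem <- file.path(dir, sprintf("margin_%03d", k - 1))
    write_mask(st, paste0(stem, ".png"))
    contours_to_geojson(st$contours, paste0(stem, ".geojson"))
  }
  manifest <- tidy.margin_sequence(seq)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
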