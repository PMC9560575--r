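#' Explicit upwind level-set propagation (numerical cross-check)
#'
#' Integrates the front-propagation problem `phi_t + v |grad phi| = 0`
#' (lesion = `{phi <= 0}`, outward motion for `v >= 0`) with a Godunov
#' upwind scheme and CFL-limited explicit time stepping, starting from the
#' signed distance to the baseline margin. This integrator shares nothing
#' with the fast-marching arrival-time solver beyond the initial condition
#' and serves as an independent numerical oracle: both propagators must
#' agree on the follow-up mask to within about one pixel.
#'
#' @inheritParams propagate
#' @param cfl CFL number in (0, 0.5].
#' @return A list with `mask` (logical follow-up mask), `phi` (final level
#'   function, mm), and `n_steps_taken`.
#' @export
level_set_propagate <- function(baseline, field, dt_years, cfl = 0.45,
                                band_px = 4) {
  stopifnot(inherits(baseline, "lesion_state"), inherits(field, "growth_field"))
  if (!grids_compatible(baseline$grid, field$grid)) {
    stop("baseline and field grids differ", call. = FALSE)
  }
  grid <- baseline$grid
  h <- grid$pixel_size_mm
  v <- field$values
  vmax <- max(v)
  # subpixel signed distance near the margin, mask-based farther away
  phi <- ifelse(baseline$mask, -1, 1) * (signed_distance_abs(baseline$mask)) * h
  bd <- band_distance_cpp(
    baseline$contours$chains, grid$width_px, grid$height_px,
    grid$origin_mm[1], grid$origin_mm[2], h, band_px * h
  )
  in_band <- is.finite(bd)
  phi[in_band] <- ifelse(baseline$mask[in_band], -1, 1) * bd[in_band]
  if (vmax <= 0) {
    return(list(mask = baseline$mask, phi = phi, n_steps_taken = 0L))
  }
  nt <- ceiling(dt_years / (cfl * h / vmax))
  dtt <- dt_years / nt
  nx <- nrow(phi)
  ny <- ncol(phi)
  for (k in seq_len(nt)) {
    dmx <- (phi - phi[c(1, seq_len(nx - 1)), , drop = FALSE]) / h
    dpx <- (phi[c(seq_len(nx - 1) + 1, nx), , drop = FALSE] - phi) / h
    dmy <- (phi - phi[, c(1, seq_len(ny - 1)), drop = FALSE]) / h
    dpy <- (phi[, c(seq_len(ny - 1) + 1, ny), drop = FALSE] - phi) / h
    g <- sqrt(pmax(dmx, 0)^2 + pmin(dpx, 0)^2 +
                pmax(dmy, 0)^2 + pmin(dpy, 0)^2)
    phi <- phi - dtt * v * g
  }
  list(mask = phi <= 0, phi = phi, n_steps_taken = nt)
}

# unsigned pixel distance to the opposite phase, offset so the zero level
# sits halfway between foreground and background pixel centres
signed_distance_abs <- function(mask) {
  d_to_fg <- edt_cpp(mask)
  d_to_bg <- edt_cpp(!mask)
  ifelse(mask, pmax(d_to_bg - 0.5, 0), pmax(d_to_fg - 0.5, 0))
}
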