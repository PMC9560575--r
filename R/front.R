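#' Growth field
#'
#' A nonnegative scalar raster (mm/year) giving the local, geometry-
#' independent rate of margin advance; it encodes the state of the
#' chorioretinal milieu. Fields are time-invariant.
#'
#' @param grid A [pixel_grid()].
#' @param values Matrix on `grid`, or a single number for an isotropic
#'   field. All values must be finite and nonnegative.
#' @return An object of class `growth_field`.
#' @export
growth_field <- function(grid, values) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (length(values) == 1) {
    values <- matrix(as.numeric(values), grid$width_px, grid$height_px)
  }
  stopifnot(nrow(values) == grid$width_px, ncol(values) == grid$height_px)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("growth field values must be finite and nonnegative", call. = FALSE)
  }
  structure(list(grid = grid, values = values), class = "growth_field")
}

#' @export
print.growth_field <- function(x, ...) {
  cat(sprintf(
    "<growth_field> %d x %d px, range [%.4g, %.4g] mm/yr\n",
    x$grid$width_px, x$grid$height_px, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Arrival time of the atrophy front
#'
#' Solves the stationary eikonal problem `|grad T| = 1/v` with `T = 0` on
#' the baseline margin, using a second-order fast-marching method. This is
#' the arrival-time formulation of the atrophy-front model for
#' time-invariant, nonnegative growth fields: thresholding `{T <= t}`
#' yields the lesion at time `t` after baseline. The solver is seeded with
#' the signed distance to the subpixel baseline contour divided by the
#' local speed, so the baseline geometry is honoured at subpixel precision.
#' Pixels with `v = 0` are impermeable (`T = +Inf`).
#'
#' @param baseline A [lesion_state()].
#' @param field A [growth_field()] on the same grid.
#' @param band_px Half-width (pixels) of the initialisation band around the
#'   baseline margin.
#' @return An object of class `arrival_time` with elements `grid`, `times`
#'   (matrix, years; negative inside the baseline, `Inf` where
#'   unreachable), `baseline`, and `field`.
#' @export
arrival_time <- function(baseline, field, band_px = 4) {
  stopifnot(inherits(baseline, "lesion_state"), inherits(field, "growth_field"))
  if (!grids_compatible(baseline$grid, field$grid)) {
    stop("baseline and field grids differ", call. = FALSE)
  }
  grid <- baseline$grid
  h <- grid$pixel_size_mm
  bd <- band_distance_cpp(
    baseline$contours$chains, grid$width_px, grid$height_px,
    grid$origin_mm[1], grid$origin_mm[2], h, band_px * h
  )
  v <- field$values
  init <- matrix(NA_real_, grid$width_px, grid$height_px)
  in_band <- is.finite(bd)
  sgn <- ifelse(baseline$mask, -1, 1)
  ok <- in_band & v > 0
  init[ok] <- sgn[ok] * bd[ok] / v[ok]
  # interior pixels (beyond the band, or stalled where v = 0) must be
  # accepted with large negative times so the outward march never walks
  # back into the lesion
  deep <- baseline$mask & !ok
  init[deep] <- -1e6
  times <- fmm_arrival_cpp(v, init, h, TRUE)
  structure(
    list(grid = grid, times = times, baseline = baseline, field = field),
    class = "arrival_time"
  )
}

#' @export
print.arrival_time <- function(x, ...) {
  fin <- x$times[is.finite(x$times) & x$times > 0]
  cat(sprintf(
    "<arrival_time> %d x %d px; reachable front times up to %.3g yr\n",
    x$grid$width_px, x$grid$height_px,
    if (length(fin)) max(fin) else NA_real_
  ))
  invisible(x)
}

# smallest arrival time on the grid border (years); propagation beyond it
# would be clipped
border_arrival <- function(at) {
  tm <- at$times
  min(tm[1, ], tm[nrow(tm), ], tm[, 1], tm[, ncol(tm)])
}

# lesion state at time t (years after baseline) from an arrival-time raster
state_at <- function(at, t) {
  mask <- at$times <= t
  cs <- contours_from_values(-at$times, at$grid, level = -t)
  lesion_state(at$grid, mask, cs, time_years = at$baseline$time_years + t)
}

#' Propagate a lesion margin under a growth field
#'
#' Produces a time-ordered sequence of lesion states at `n_steps + 1`
#' equally spaced times between baseline and `dt_years`, by thresholding
#' the fast-marching arrival-time raster. Intrafocus and interfoci merging
#' arise naturally as level sets join. Errors if the front would reach the
#' grid border within `dt_years` (the growth would be clipped).
#'
#' @inheritParams arrival_time
#' @param dt_years Follow-up interval (years), positive.
#' @param n_steps Number of propagation intervals (at least 2); the saved
#'   margins are used as the position-time sample for the ground-truth
#'   growth rate.
#' @return An object of class `margin_sequence` with elements `states`
#'   (list of [lesion_state()]), `field`, `dt_years`, and `arrival`.
#' @export
propagate <- function(baseline, field, dt_years, n_steps = 10, band_px = 4) {
  stopifnot(dt_years > 0, n_steps >= 2)
  at <- arrival_time(baseline, field, band_px = band_px)
  propagate_arrival(at, dt_years, n_steps)
}

#' @rdname propagate
#' @param at An [arrival_time()] object (allows reusing one eikonal solve
#'   for several follow-up intervals).
#' @export
propagate_arrival <- function(at, dt_years, n_steps = 10) {
  stopifnot(inherits(at, "arrival_time"), dt_years > 0, n_steps >= 2)
  if (border_arrival(at) <= dt_years) {
    stop("front reaches the grid border before dt_years; enlarge the grid padding",
         call. = FALSE)
  }
  ts <- seq(0, dt_years, length.out = n_steps + 1)
  states <- lapply(ts, function(t) state_at(at, t))
  structure(
    list(states = states, field = at$field, dt_years = dt_years, arrival = at),
    class = "margin_sequence"
  )
}

#' @export
print.margin_sequence <- function(x, ...) {
  areas <- vapply(x$states, function(s) contour_area(s$contours), numeric(1))
  cat(sprintf(
    "<margin_sequence> %d states over %g yr; area %.4g -> %.4g mm^2\n",
    length(x$states), x$dt_years, areas[1], areas[length(areas)]
  ))
  invisible(x)
}

#' Ground-truth global length-type growth rate
#'
#' The length-type growth rate is the position-time average of the growth
#' field along the evolving margin:
#' `Lambda = (sum_k oint_{margin(t_k)} v ds) / (sum_k oint_{margin(t_k)} ds)`,
#' with the field sampled by bilinear interpolation at the contour vertices
#' and trapezoidal arclength weights. Margin segments that merge away stop
#' contributing automatically because only the active front's contours
#' exist at each saved time. For an isotropic field `Lambda` equals the
#' field value exactly.
#'
#' @param seq A [margin_sequence()].
#' @return An object of class `ground_truth_rate`: list with
#'   `lambda_mm_per_year` and `per_step_means` (tibble of time,
#'   arclength-weighted mean speed, and margin arclength).
#' @export
ground_truth_lambda <- function(seq) {
  stopifnot(inherits(seq, "margin_sequence"))
  grid <- seq$field$grid
  v <- seq$field$values
  num_tot <- 0
  den_tot <- 0
  steps <- lapply(seq$states, function(st) {
    num <- 0
    den <- 0
    for (ch in st$contours$chains) {
      vs <- bilinear_at(v, grid, ch[, 1], ch[, 2])
      seg <- sqrt(diff(ch[, 1])^2 + diff(ch[, 2])^2)
      vmid <- (vs[-length(vs)] + vs[-1]) / 2
      num <- num + sum(vmid * seg)
      den <- den + sum(seg)
    }
    c(time = st$time_years, num = num, den = den)
  })
  m <- do.call(rbind, steps)
  num_tot <- sum(m[, "num"])
  den_tot <- sum(m[, "den"])
  if (den_tot <= 0) stop("degenerate margin: zero total arclength", call. = FALSE)
  structure(
    list(
      lambda_mm_per_year = num_tot / den_tot,
      per_step_means = tibble::tibble(
        time_years = m[, "time"],
        mean_speed = m[, "num"] / m[, "den"],
        arclength_mm = m[, "den"]
      )
    ),
    class = "ground_truth_rate"
  )
}

#' @export
print.ground_truth_rate <- function(x, ...) {
  cat(sprintf("<ground_truth_rate> Lambda = %.5g mm/yr (%d margin samples)\n",
              x$lambda_mm_per_year, nrow(x$per_step_means)))
  invisible(x)
}

#' Rescale a growth field to reach a target ground-truth growth rate
#'
#' Finds `c` such that the ground-truth rate of `c * field` propagated from
#' `baseline` over `dt_years` equals `target_lambda`. For isotropic
#' (constant) fields the scaling is exact and needs no propagation; for
#' anisotropic fields the nearly linear relation between `c` and `Lambda`
#' is solved by damped ratio iteration.
#'
#' @inheritParams propagate
#' @param target_lambda Target ground-truth rate, mm/year (positive).
#' @param tol Convergence tolerance on `Lambda`, mm/year.
#' @param max_iter Iteration cap.
#' @return A [growth_field()] with attribute `achieved_lambda`.
#' @export
scale_field_to_lambda <- function(baseline, field, dt_years, target_lambda,
                                  n_steps = 10, tol = 1e-3, max_iter = 50) {
  stopifnot(inherits(field, "growth_field"))
  if (!is.finite(target_lambda) || target_lambda <= 0) {
    stop("target_lambda must be positive", call. = FALSE)
  }
  vals <- field$values
  vmax <- max(vals)
  if (vmax <= 0) stop("field is identically zero", call. = FALSE)
  if (vmax - min(vals) < 1e-12 * vmax) {
    out <- growth_field(field$grid, vals * (target_lambda / vals[1, 1]))
    attr(out, "achieved_lambda") <- target_lambda
    return(out)
  }
  measure <- function(cc) {
    f <- growth_field(field$grid, vals * cc)
    ground_truth_lambda(propagate(baseline, f, dt_years, n_steps))$lambda_mm_per_year
  }
  cc <- target_lambda / measure(1)
  for (it in seq_len(max_iter)) {
    lam <- measure(cc)
    if (abs(lam - target_lambda) <= tol) {
      out <- growth_field(field$grid, vals * cc)
      attr(out, "achieved_lambda") <- lam
      return(out)
    }
    cc <- cc * target_lambda / lam
  }
  stop("scale_field_to_lambda did not converge in ", max_iter, " iterations",
       call. = FALSE)
}
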