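#' Tip position track of a trajectory
#'
#' @param traj a `sprout_trajectory` from [run_simulation()].
#' @param recompute re-run [locate_tip()] on the stored snapshots instead of
#'   returning the track recorded during the run.
#' @return a data.frame (class `tip_track`) with columns `time_h`, `x_px`,
#'   `y_px`, strictly increasing in time.
#' @export
tip_track <- function(traj, recompute = FALSE) {
  stopifnot(inherits(traj, "sprout_trajectory"))
  if (recompute) {
    rows <- lapply(seq_along(traj$times_h), function(k) {
      tp <- locate_tip(traj$snapshots[[k]], traj$direction)
      data.frame(time_h = traj$times_h[k], x_px = tp$x, y_px = tp$y)
    })
    tr <- do.call(rbind, rows)
  } else tr <- traj$tip
  if (any(is.na(tr$y_px))) stop("snapshot with no cell sites in track")
  class(tr) <- c("tip_track", "data.frame")
  tr
}

.track_y_at <- function(track, t_h) {
  if (t_h < min(track$time_h) - 1e-9 || t_h > max(track$time_h) + 1e-9)
    stop(sprintf("time %.4g h outside the track span [%.4g, %.4g]",
                 t_h, min(track$time_h), max(track$time_h)))
  approx(track$time_h, track$y_px, xout = t_h, rule = 2)$y
}

#' Mean tip y-velocity (signed, um/h)
#'
#' `(y(t_end) - y(t_start)) * dx_um / (t_end - t_start)`. The sign follows the
#' grid axis: advancement toward decreasing y gives a negative velocity.
#'
#' @param track a [tip_track()].
#' @param t_start_h,t_end_h bracketing times (hours), defaulting to the full
#'   track span. `t_end_h` must exceed `t_start_h`.
#' @param grid a [grid_spec()] supplying `dx_um`.
#' @return signed velocity in micrometres per hour.
#' @export
mean_tip_velocity <- function(track, t_start_h = NULL, t_end_h = NULL, grid) {
  t_start_h <- t_start_h %||% min(track$time_h)
  t_end_h <- t_end_h %||% max(track$time_h)
  if (t_end_h <= t_start_h) stop("t_end_h must exceed t_start_h")
  (.track_y_at(track, t_end_h) - .track_y_at(track, t_start_h)) *
    grid$dx_um / (t_end_h - t_start_h)
}

#' Net tip migration distance (um)
#'
#' @param track a [tip_track()].
#' @param t_hours elapsed time (hours) within the track span.
#' @param grid a [grid_spec()].
#' @return `|y(t) - y(0)| * dx_um` in micrometres.
#' @export
migration_distance <- function(track, t_hours, grid) {
  abs(.track_y_at(track, t_hours) - .track_y_at(track, min(track$time_h))) *
    grid$dx_um
}

#' Tip path tortuosity
#'
#' Path length of the (x, y) tip track divided by its net displacement.
#' 1 for a straight path; larger for meandering ones.
#'
#' @param track a [tip_track()].
#' @return dimensionless tortuosity (>= 1 up to discretization noise).
#' @export
tip_tortuosity <- function(track) {
  dx <- diff(track$x_px); dy <- diff(track$y_px)
  pl <- sum(sqrt(dx^2 + dy^2))
  net <- sqrt((track$x_px[nrow(track)] - track$x_px[1])^2 +
              (track$y_px[nrow(track)] - track$y_px[1])^2)
  if (net == 0) return(Inf)
  pl / net
}

#' Cell-volume flux between two snapshots
#'
#' The migration flux `(sum phi(t) - sum phi(t0)) / (t - t0)` measuring net
#' phase injected by the reservoir and the environment term; also reported
#' as a domain fraction per hour, `raw / (2 * N_sites)` (the factor 2 is the
#' phase span from -1 to +1), which is the normalization on which the
#' canonical printed rates (~0.67e-3 1/h) live.
#'
#' @param traj a `sprout_trajectory`.
#' @param t0_h,t_h snapshot times in hours; both must be present in the
#'   trajectory (to 1e-6 h).
#' @return a `flux_result` list: `t0_h`, `t_h`, `raw_rate`, `fraction_rate`.
#' @export
volume_flux <- function(traj, t0_h, t_h) {
  stopifnot(inherits(traj, "sprout_trajectory"))
  find <- function(t) {
    k <- which(abs(traj$times_h - t) < 1e-6)
    if (!length(k)) stop(sprintf("missing snapshot at t = %g h", t))
    k[1]
  }
  k0 <- find(t0_h); k1 <- find(t_h)
  if (t_h <= t0_h) stop("t_h must exceed t0_h")
  raw <- (traj$sum_phi[k1] - traj$sum_phi[k0]) / (t_h - t0_h)
  n_sites <- length(traj$snapshots[[1]])
  structure(list(t0_h = t0_h, t_h = t_h, raw_rate = raw,
                 fraction_rate = raw / (2 * n_sites)),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> [%g, %g] h: raw %.4g /h, fraction %.4g /h\n",
              x$t0_h, x$t_h, x$raw_rate, x$fraction_rate))
  invisible(x)
}

#' Volume flux between tip crossings (summary-table convention)
#'
#' Evaluates [volume_flux()] between the first snapshots at which the tip has
#' crossed `y_first` and `y_second` (advancement toward decreasing y).
#'
#' @param traj a `sprout_trajectory`.
#' @param y_first,y_second crossing thresholds in pixels (defaults 180, 25).
#' @return a `flux_result`.
#' @export
flux_between_crossings <- function(traj, y_first = 180, y_second = 25) {
  tr <- tip_track(traj)
  cmp <- if (traj$direction < 0) `<=` else `>=`
  k0 <- which(cmp(tr$y_px, y_first))
  k1 <- which(cmp(tr$y_px, y_second))
  if (!length(k0) || !length(k1))
    stop("tip never crossed the requested y levels")
  volume_flux(traj, tr$time_h[k0[1]], tr$time_h[k1[1]])
}

#' Mean pore size by local thickness (um)
#'
#' Binarizes pore space as `h < pore_threshold`, computes the local thickness
#' of each pore site (diameter of the largest pore-inscribed disc covering
#' it, via an exact Euclidean distance transform), and returns the mean over
#' pore sites converted to micrometres. Rotation-invariant up to pixelation;
#' on a straight corridor of width w it returns w within one pixel.
#'
#' @param h hydrogel density [scalar_field()] or matrix in [0, 1].
#' @param pore_threshold binarization threshold (default 0.5).
#' @param grid a [grid_spec()] supplying `dx_um`.
#' @return mean pore diameter in micrometres.
#' @export
measure_mean_pore_size <- function(h, pore_threshold = 0.5, grid) {
  v <- field_values(h)
  pore <- v < pore_threshold
  if (!any(pore)) stop("no pore sites below the threshold")
  if (all(pore)) {
    warning("all-pore field: returning the domain-scale upper bound")
    return(sqrt(nrow(v)^2 + ncol(v)^2) * grid$dx_um)
  }
  thick <- cpp_local_thickness(pore)
  mean(thick[pore]) * grid$dx_um
}
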