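#' Tip-cell sensing and MMP degradation parameters
#'
#' The leading tip cell looks `sensing_radius_px` ahead (~ two cell
#' diameters, 40 um at the canonical calibration), scans candidate headings
#' within `heading_halfangle_deg` of the local chemoattractant ascent, picks
#' the heading with the least hydrogel in its look-ahead window, and deposits
#' matrix metalloproteinases there as a Gaussian footprint of scale
#' `sigma_px` and amplitude `power`, clearing matrix density.
#'
#' @param sensing_radius_px look-ahead distance in pixels (>= 1).
#' @param power degradative power d in [0, 1]; 0 reproduces the fundamental
#'   model exactly.
#' @param sigma_px Gaussian MMP footprint scale in pixels.
#' @param cadence_steps integration steps between events; `NULL` = one event
#'   per 0.275 h of simulated time (resolved at run time).
#' @param heading_halfangle_deg half-angle of the candidate heading fan.
#' @param heading_step_deg angular resolution of the fan.
#' @param enabled logical master switch.
#' @return an object of class `degradation_params`.
#' @export
degradation_params <- function(sensing_radius_px = 10, power = 0.2,
                               sigma_px = 5, cadence_steps = NULL,
                               heading_halfangle_deg = 60,
                               heading_step_deg = 15, enabled = TRUE) {
  stopifnot(sensing_radius_px >= 1, power >= 0, power <= 1, sigma_px > 0,
            heading_halfangle_deg >= 0, heading_step_deg > 0)
  if (!is.null(cadence_steps)) stopifnot(cadence_steps >= 1)
  structure(list(sensing_radius_px = sensing_radius_px, power = power,
                 sigma_px = sigma_px, cadence_steps = cadence_steps,
                 heading_halfangle_deg = heading_halfangle_deg,
                 heading_step_deg = heading_step_deg,
                 enabled = isTRUE(enabled)),
            class = "degradation_params")
}

#' Locate the tip cell
#'
#' The tip is the most advanced site of the cell region (phi >= 0) along the
#' advancement axis. Ties across equally advanced columns are broken by
#' minimal transverse distance to the cell-mask centroid, then by the
#' smallest transverse index, so detection is fully deterministic.
#'
#' @param phi matrix or [scalar_field()].
#' @param direction -1 (advance toward column 1, default) or +1.
#' @return a `tip_position` list with integer fields `x`, `y`.
#' @export
locate_tip <- function(phi, direction = -1L) {
  v <- field_values(phi)
  mask <- v >= 0
  if (!any(mask)) stop("no cell sites: phi < 0 everywhere")
  cols <- which(colSums(mask) > 0)
  jstar <- if (direction < 0) min(cols) else max(cols)
  rows <- which(mask[, jstar])
  centroid_x <- mean(row(v)[mask])
  d <- abs(rows - centroid_x)
  istar <- rows[order(d, rows)][1]
  structure(list(x = as.integer(istar), y = as.integer(jstar)),
            class = "tip_position")
}

# mean hydrogel density over the disc of radius r centered at (cx, cy),
# clipped to the grid. A disc overlapping the domain but containing no
# lattice site falls back to the nearest in-grid site; NA only when the
# disc lies entirely outside the grid.
.disc_mean <- function(h, cx, cy, r) {
  nx <- nrow(h); ny <- ncol(h)
  # sites are unit cells centred on integers: the domain extends half a
  # pixel beyond the outermost centres
  if (cx + r < 0.5 || cx - r > nx + 0.5 || cy + r < 0.5 || cy - r > ny + 0.5)
    return(NA_real_)
  i0 <- max(1L, floor(cx - r)); i1 <- min(nx, ceiling(cx + r))
  j0 <- max(1L, floor(cy - r)); j1 <- min(ny, ceiling(cy + r))
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - cx)^2, (jj - cy)^2, `+`)
  inside <- d2 <= r^2
  if (!any(inside))
    return(h[min(max(round(cx), 1), nx), min(max(round(cy), 1), ny)])
  mean(h[ii, jj, drop = FALSE][inside])
}

#' Sense the environment ahead of the tip
#'
#' Candidate headings within the fan about the local chemoattractant ascent
#' direction are scored by the mean hydrogel density over a look-ahead disc
#' of radius `sigma_px` centered `sensing_radius_px` away along the heading.
#' The minimal-score heading wins; ties go to the heading closest to straight
#' ascent. Windows are clipped at the domain boundary.
#'
#' @param env an `ecm_environment`.
#' @param tip a `tip_position` from [locate_tip()].
#' @param params a [degradation_params()].
#' @param fallback_dir unit direction used when the local chemoattractant
#'   gradient vanishes (default: straight advancement toward column 1).
#' @return a `sense_decision` list: `heading` (unit vector), `angle_deg`
#'   (relative to ascent), `target_center` (x, y), `window_scores`.
#' @export
sense_environment <- function(env, tip, params,
                              fallback_dir = c(0, -1)) {
  h <- field_values(env$hydrogel)
  nu <- field_values(env$nu_c)
  nx <- nrow(h); ny <- ncol(h)
  i <- tip$x; j <- tip$y
  gx <- (nu[min(i + 1, nx), j] - nu[max(i - 1, 1), j]) / 2
  gy <- (nu[i, min(j + 1, ny)] - nu[i, max(j - 1, 1)]) / 2
  g <- c(gx, gy)
  nrm <- sqrt(sum(g^2))
  dir0 <- if (nrm < 1e-12) fallback_dir / sqrt(sum(fallback_dir^2)) else g / nrm
  angles <- seq(-params$heading_halfangle_deg, params$heading_halfangle_deg,
                by = params$heading_step_deg)
  R <- params$sensing_radius_px
  scores <- data.frame(angle_deg = angles, cx = NA_real_, cy = NA_real_,
                       score = NA_real_)
  for (k in seq_along(angles)) {
    a <- angles[k] * pi / 180
    d <- c(cos(a) * dir0[1] - sin(a) * dir0[2],
           sin(a) * dir0[1] + cos(a) * dir0[2])
    cx <- i + R * d[1]; cy <- j + R * d[2]
    scores$cx[k] <- cx; scores$cy[k] <- cy
    scores$score[k] <- .disc_mean(h, cx, cy, params$sigma_px)
  }
  if (all(is.na(scores$score)))
    stop("sensing window fully outside the grid")
  best <- min(scores$score, na.rm = TRUE)
  cand <- which(!is.na(scores$score) & scores$score <= best + 1e-12)
  pick <- cand[order(abs(scores$angle_deg[cand]), scores$angle_deg[cand])][1]
  a <- scores$angle_deg[pick] * pi / 180
  heading <- c(cos(a) * dir0[1] - sin(a) * dir0[2],
               sin(a) * dir0[1] + cos(a) * dir0[2])
  target <- c(min(max(round(scores$cx[pick]), 1), nx),
              min(max(round(scores$cy[pick]), 1), ny))
  structure(list(heading = heading, angle_deg = scores$angle_deg[pick],
                 target_center = target, window_scores = scores),
            class = "sense_decision")
}

#' Deposit MMPs: subtract a Gaussian footprint from the hydrogel
#'
#' `h' = max(h - power * G, 0)` with `G` a unit-peak Gaussian of scale
#' `sigma_px` centered at `center`, truncated beyond 4 sigma. Hydrogel mass
#' is therefore non-increasing and never negative.
#'
#' @param h hydrogel density [scalar_field()] or matrix.
#' @param center length-2 (x, y) grid coordinate inside the grid.
#' @param params a [degradation_params()].
#' @return the degraded hydrogel field.
#' @export
deposit_mmp <- function(h, center, params) {
  v <- field_values(h)
  nx <- nrow(v); ny <- ncol(v)
  cx <- center[1]; cy <- center[2]
  if (cx < 1 || cx > nx || cy < 1 || cy > ny) stop("center outside grid")
  if (params$power == 0) return(scalar_field(v, "hydrogel_density"))
  s <- params$sigma_px
  w <- ceiling(4 * s)
  ii <- max(1, floor(cx - w)):min(nx, ceiling(cx + w))
  jj <- max(1, floor(cy - w)):min(ny, ceiling(cy + w))
  d2 <- outer((ii - cx)^2, (jj - cy)^2, `+`)
  G <- exp(-d2 / (2 * s^2))
  G[d2 > (4 * s)^2] <- 0
  v[ii, jj] <- pmax(v[ii, jj] - params$power * G, 0)
  scalar_field(v, "hydrogel_density")
}

#' One tip sensing + degradation event
#'
#' Locates the tip, senses the lowest-matrix heading toward the
#' chemoattractant, deposits MMPs at the chosen target, and recomposes C0
#' from the mutated hydrogel (same gamma and floor). Total hydrogel mass is
#' non-increasing.
#'
#' @param state a [phase_state()].
#' @param env an `ecm_environment`.
#' @param params a [degradation_params()].
#' @param direction advancement direction (see [locate_tip()]).
#' @return list with the mutated `env`, the `decision` and the `tip`.
#' @export
degradation_event <- function(state, env, params, direction = -1L) {
  tip <- locate_tip(state$phi, direction)
  dec <- sense_environment(env, tip, params,
                           fallback_dir = c(0, direction))
  env$hydrogel <- deposit_mmp(env$hydrogel, dec$target_center, params)
  env <- .recompose_C0(env)
  list(env = env, decision = dec, tip = tip)
}
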