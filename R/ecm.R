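#' Synthetic porous-ECM generator specification
#'
#' The synthetic matrix stands in for a confocal image of a large-pore fibrin
#' hydrogel: a Gaussian-smoothed white-noise field thresholded at the quantile
#' matching the target porosity, giving a binary density field (1 = matrix,
#' 0 = pore). The smoothing scale `correlation_length_px` sets the pore scale;
#' leave it `NULL` to have [generate_synthetic_ecm()] calibrate it by
#' bisection against [measure_mean_pore_size()] so the mean pore diameter hits
#' `target_mean_pore_um` (default 40 um, the measured mean pore size of the
#' hydrogel being emulated).
#'
#' @param porosity target pore-area fraction, in (0, 1).
#' @param target_mean_pore_um desired mean pore diameter, micrometres.
#' @param correlation_length_px Gaussian smoothing sd of the random field in
#'   pixels, or `NULL` to calibrate.
#' @param seed integer RNG seed; identical spec + seed gives identical fields.
#' @return an object of class `ecm_gen_spec`.
#' @export
ecm_gen_spec <- function(porosity = 0.5, target_mean_pore_um = 40,
                         correlation_length_px = NULL, seed = 1L) {
  stopifnot(porosity > 0, porosity < 1, target_mean_pore_um > 0)
  if (!is.null(correlation_length_px)) stopifnot(correlation_length_px > 0)
  structure(list(porosity = porosity,
                 target_mean_pore_um = target_mean_pore_um,
                 correlation_length_px = correlation_length_px,
                 seed = as.integer(seed)),
            class = "ecm_gen_spec")
}

# Periodic Gaussian smoothing by FFT; sigma in pixels.
.gauss_smooth_fft <- function(z, sigma) {
  n1 <- nrow(z); n2 <- ncol(z)
  k1 <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) * (2 * pi / n1)
  k2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) * (2 * pi / n2)
  damp <- exp(-0.5 * sigma^2 * outer(k1^2, k2^2, `+`))
  Re(fft(fft(z) * damp, inverse = TRUE)) / (n1 * n2)
}

.raw_ecm_field <- function(porosity, sigma, seed, grid) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  z <- matrix(rnorm(grid$nx * grid$ny), grid$nx, grid$ny)
  zs <- .gauss_smooth_fft(z, sigma)
  thr <- quantile(zs, porosity)
  matrix(as.numeric(zs >= thr), grid$nx, grid$ny)
}

#' Generate a synthetic porous hydrogel density field
#'
#' @param spec an [ecm_gen_spec()].
#' @param grid a [grid_spec()].
#' @param calibration_seeds number of seeds averaged during calibration when
#'   `spec$correlation_length_px` is `NULL`.
#' @return a [scalar_field()] with role `hydrogel_density`, values in
#'   \{0, 1\} (1 = densest matrix, 0 = pore).
#' @seealso [calibrate_ecm()], [measure_mean_pore_size()]
#' @export
generate_synthetic_ecm <- function(spec, grid, calibration_seeds = 3L) {
  stopifnot(inherits(spec, "ecm_gen_spec"), inherits(grid, "grid_spec"))
  if (is.null(spec$correlation_length_px))
    spec <- calibrate_ecm(spec, grid, n_seeds = calibration_seeds)
  h <- .raw_ecm_field(spec$porosity, spec$correlation_length_px, spec$seed, grid)
  scalar_field(h, "hydrogel_density", grid)
}

#' Calibrate the ECM generator correlation length
#'
#' Bisects the smoothing scale so that the mean pore diameter of generated
#' fields (averaged over `n_seeds` seeds derived from `spec$seed`) matches
#' `spec$target_mean_pore_um` within `tol_frac`. Mean pore size is a
#' monotone increasing function of the smoothing scale at fixed porosity.
#'
#' @param spec an [ecm_gen_spec()].
#' @param grid a [grid_spec()].
#' @param n_seeds seeds averaged per candidate scale.
#' @param tol_frac relative tolerance on the achieved mean pore size.
#' @param max_iter bisection iteration cap.
#' @return the spec with `correlation_length_px` filled in.
#' @export
calibrate_ecm <- function(spec, grid, n_seeds = 3L, tol_frac = 0.02,
                          max_iter = 40L) {
  stopifnot(inherits(spec, "ecm_gen_spec"))
  seeds <- spec$seed + seq_len(n_seeds) * 7919L
  measure_at <- function(sigma) {
    mean(vapply(seeds, function(s) {
      h <- .raw_ecm_field(spec$porosity, sigma, s, grid)
      measure_mean_pore_size(scalar_field(h, "hydrogel_density", grid),
                             grid = grid)
    }, numeric(1)))
  }
  lo <- 0.4; hi <- min(grid$nx, grid$ny) / 8
  target <- spec$target_mean_pore_um
  m_lo <- measure_at(lo); m_hi <- measure_at(hi)
  if (target < m_lo || target > m_hi)
    stop(sprintf(paste0("cannot calibrate: target %.3g um outside achievable ",
                        "range [%.3g, %.3g] um at porosity %.2f"),
                 target, m_lo, m_hi, spec$porosity))
  for (it in seq_len(max_iter)) {
    mid <- 0.5 * (lo + hi)
    m <- measure_at(mid)
    if (abs(m - target) / target <= tol_frac) {
      spec$correlation_length_px <- mid
      return(spec)
    }
    if (m < target) lo <- mid else hi <- mid
  }
  spec$correlation_length_px <- 0.5 * (lo + hi)
  spec
}

#' Corridor specification for carving an open path
#'
#' @param waypoints numeric matrix with columns (x, y): ordered grid
#'   coordinates of the polyline.
#' @param width_px corridor width in pixels (>= 1).
#' @return an object of class `path_spec`.
#' @export
path_spec <- function(waypoints, width_px = 10) {
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 1) stop("empty waypoint list")
  stopifnot(ncol(waypoints) == 2, width_px >= 1)
  structure(list(waypoints = waypoints, width_px = width_px),
            class = "path_spec")
}

# Distance from every grid site to segment (a, b); a, b length-2 (x, y).
.dist_to_segment <- function(nx, ny, a, b) {
  xi <- matrix(seq_len(nx), nx, ny)
  yj <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((xi - a[1])^2 + (yj - a[2])^2))
  t <- ((xi - a[1]) * ab[1] + (yj - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((xi - (a[1] + t * ab[1]))^2 + (yj - (a[2] + t * ab[2]))^2)
}

#' Carve a zero-density corridor through a hydrogel field
#'
#' Sets density to 0 within `width_px / 2` of the waypoint polyline (the
#' union of discs swept along the segments), mimicking an open biomimetic
#' pore cells can follow. Idempotent on pore space.
#'
#' @param h hydrogel density [scalar_field()].
#' @param path a [path_spec()].
#' @return the carved hydrogel field.
#' @export
carve_open_path <- function(h, path) {
  stopifnot(inherits(path, "path_spec"))
  v <- field_values(h)
  nx <- nrow(v); ny <- ncol(v)
  wp <- path$waypoints
  if (any(wp[, 1] < 1 | wp[, 1] > nx | wp[, 2] < 1 | wp[, 2] > ny))
    stop("waypoints outside grid")
  d <- .dist_to_segment(nx, ny, wp[1, ], wp[1, ])
  if (nrow(wp) > 1)
    for (s in seq_len(nrow(wp) - 1))
      d <- pmin(d, .dist_to_segment(nx, ny, wp[s, ], wp[s + 1, ]))
  v[d <= path$width_px / 2] <- 0
  scalar_field(v, "hydrogel_density")
}
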