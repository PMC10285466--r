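# Independent oracles: naive nested-loop implementations of the discrete
# operators, written directly from the governing equations and kept free of
# any package internals.

# mirror-closure neighbour value
.nb <- function(f, i, j) {
  nx <- nrow(f); ny <- ncol(f)
  i <- min(max(i, 1), nx); j <- min(max(j, 1), ny)
  f[i, j]
}

naive_laplacian <- function(f, dx = 1) {
  nx <- nrow(f); ny <- ncol(f)
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    out[i, j] <- (.nb(f, i + 1, j) + .nb(f, i - 1, j) +
                  .nb(f, i, j + 1) + .nb(f, i, j - 1) - 4 * f[i, j]) / dx^2
  }
  out
}

naive_rhs <- function(phi, C0, M = 1, eps = 1, dx = 1, conserved = FALSE) {
  B <- eps * C0 * (phi^2 - 1)
  lap_phi <- naive_laplacian(phi, dx)
  lap_B <- naive_laplacian(B, dx)
  if (conserved) {
    mu <- -phi + phi^3 - eps^2 * lap_phi + 2 * phi * eps * C0 * B - eps^2 * lap_B
    M * naive_laplacian(mu, dx)
  } else {
    mu <- -phi + phi^3 - eps^2 * lap_phi
    M * naive_laplacian(mu, dx) + 2 * phi * eps * C0 * B - eps^2 * lap_B
  }
}

# brute-force point-in-corridor test for carve_open_path
naive_in_corridor <- function(nx, ny, waypoints, width) {
  seg_dist <- function(p, a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) return(sqrt(sum((p - a)^2)))
    t <- max(0, min(1, sum((p - a) * ab) / len2))
    sqrt(sum((p - a - t * ab)^2))
  }
  m <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    d <- Inf
    if (nrow(waypoints) == 1) {
      d <- seg_dist(c(i, j), waypoints[1, ], waypoints[1, ])
    } else {
      for (s in seq_len(nrow(waypoints) - 1))
        d <- min(d, seg_dist(c(i, j), waypoints[s, ], waypoints[s + 1, ]))
    }
    m[i, j] <- d <= width / 2
  }
  m
}

# small helper environments
uniform_env <- function(nx, ny, c0 = 0, grid = NULL) {
  compose_environment(scalar_field(matrix(c0, nx, ny), "nu_c"),
                      scalar_field(matrix(0, nx, ny), "hydrogel_density"),
                      gamma = 0.5, floor = -1, grid = grid)
}

# a trajectory object built by hand (for metrics unit tests)
fake_trajectory <- function(snapshots, times_h, grid, direction = -1L) {
  tips <- do.call(rbind, lapply(seq_along(snapshots), function(k) {
    tp <- tryCatch(locate_tip(snapshots[[k]], direction),
                   error = function(e) list(x = NA_real_, y = NA_real_))
    data.frame(time_h = times_h[k], x_px = tp$x, y_px = tp$y)
  }))
  structure(list(times_h = times_h, snapshots = snapshots,
                 sum_phi = vapply(snapshots, sum, numeric(1)),
                 tip = tips, events = NULL, env_initial = NULL,
                 env_final = NULL, grid = grid, params = model_params(),
                 direction = direction, dx = 1),
            class = "sprout_trajectory")
}
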