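test_that("locate_tip finds the most advanced cell site with deterministic ties", {
  phi <- matrix(-1, 20, 20)
  phi[10, 12:20] <- 1          # single finger advancing toward column 1
  tp <- locate_tip(phi, -1L)
  expect_equal(c(tp$x, tp$y), c(10L, 12L))

  expect_error(locate_tip(matrix(-1, 5, 5)), "no cell sites")

  # two equally advanced columns; centroid closer to the left column
  phi2 <- matrix(-1, 21, 20)
  phi2[5, 10:20] <- 1
  phi2[15, 10:20] <- 1
  phi2[2:8, 18:20] <- 1        # extra mass drags the centroid left
  tp2 <- locate_tip(phi2, -1L)
  expect_equal(c(tp2$x, tp2$y), c(5L, 10L))

  # exhaustive check of the tie-break rule on the advanced row
  mask <- field_values(phi2) >= 0
  front <- which(mask[, 10])
  centroid <- mean(row(mask)[mask])
  expect_equal(tp2$x, front[order(abs(front - centroid), front)][1])

  # +1 direction mirrors the search
  phi3 <- matrix(-1, 10, 10); phi3[4, 1:6] <- 1
  expect_equal(locate_tip(phi3, 1L)$y, 6L)
})

test_that("sensing picks the clearest heading toward the chemoattractant", {
  g <- grid_spec(40L, 40L)
  nu <- make_gradient(chemotactic_spec("linear"), g)
  dp <- degradation_params(sensing_radius_px = 8, sigma_px = 3)
  tip <- structure(list(x = 20L, y = 25L), class = "tip_position")

  # uniform matrix: tie-break gives straight ascent (angle 0)
  env_u <- compose_environment(nu, scalar_field(matrix(0.6, 40, 40),
                                                "hydrogel_density"))
  dec <- sense_environment(env_u, tip, dp)
  expect_equal(dec$angle_deg, 0)
  # ascent is toward decreasing y
  expect_equal(dec$heading, c(0, -1), tolerance = 1e-12)
  expect_lte(sqrt(sum((dec$target_center - c(tip$x, tip$y))^2)),
             dp$sensing_radius_px + 1)

  # dense blob ahead on one side: heading deviates to the clear side.
  # Ahead = decreasing y; put the blob at smaller x -> deviate to larger x.
  h <- matrix(0.3, 40, 40)
  h[10:18, 12:22] <- 1
  env_b <- compose_environment(nu, scalar_field(h, "hydrogel_density"))
  dec_b <- sense_environment(env_b, tip, dp)
  expect_gt(dec_b$heading[1], 0)
  # brute-force argmin over the reported window scores agrees
  ws <- dec_b$window_scores
  expect_equal(dec_b$angle_deg,
               ws$angle_deg[which.min(ws$score)])

  # tip at the domain edge: window clipped, decision still returned
  tip_e <- structure(list(x = 1L, y = 2L), class = "tip_position")
  dec_e <- sense_environment(env_b, tip_e, dp)
  expect_true(is.finite(dec_e$angle_deg))
})

test_that("MMP deposition is a clamped Gaussian subtraction", {
  g <- grid_spec(40L, 40L)
  h <- scalar_field(matrix(0.8, 40, 40), "hydrogel_density")
  dp <- degradation_params(power = 0.2, sigma_px = 3)

  # power 0: identity
  h0 <- deposit_mmp(h, c(20, 20), degradation_params(power = 0))
  expect_equal(field_values(h0), field_values(h))

  # centre site depletes by exactly the power; clamped at 0
  h1 <- deposit_mmp(scalar_field(matrix(0.15, 40, 40), "hydrogel_density"),
                    c(20, 20), dp)
  expect_equal(h1[20, 20], 0)
  h2 <- deposit_mmp(h, c(20, 20), dp)
  expect_equal(h2[20, 20], 0.6)

  # no change beyond ~4 sigma
  far <- field_values(h2)[abs(row(h2) - 20) > 13 | abs(col(h2) - 20) > 13]
  expect_true(all(far == 0.8))

  # static tip, k deposits: centre density = max(h0 - 0.2 k, 0)
  hk <- scalar_field(matrix(1, 40, 40), "hydrogel_density")
  centre <- numeric(10)
  for (k in 1:10) {
    hk <- deposit_mmp(hk, c(20, 20), dp)
    centre[k] <- hk[20, 20]
  }
  expect_equal(centre, pmax(1 - 0.2 * (1:10), 0))

  expect_error(deposit_mmp(h, c(99, 20), dp), "outside grid")
})

test_that("degradation events deplete hydrogel monotonically", {
  g <- grid_spec(48L, 48L)
  h <- generate_synthetic_ecm(ecm_gen_spec(0.5, 40, 3, seed = 2L), g)
  nu <- make_gradient(chemotactic_spec("linear"), g)
  env <- compose_environment(nu, h, grid = g)
  phi <- matrix(-1, 48, 48); phi[22:26, 30:48] <- 1
  st <- phase_state(phi)
  dp <- degradation_params(power = 0.2, sigma_px = 3, sensing_radius_px = 6)
  mass <- sum(field_values(env$hydrogel))
  for (k in 1:8) {
    ev <- degradation_event(st, env, dp)
    env <- ev$env
    m2 <- sum(field_values(env$hydrogel))
    expect_lte(m2, mass)
    expect_true(all(field_values(env$hydrogel) >= 0))
    mass <- m2
  }
  # C0 recomposed from the mutated hydrogel with the same gamma/floor
  expect_equal(field_values(env$C0),
               pmax(field_values(env$nu_c) -
                    env$gamma * field_values(env$hydrogel), env$floor))
})

test_that("zero degradative power reproduces the fundamental model bit-for-bit", {
  g <- grid_spec(32L, 32L, dx_um = 24, time_unit_h = 1.7e-2, dt = 5e-3)
  h <- generate_synthetic_ecm(ecm_gen_spec(0.5, 80, 2.5, seed = 3L), g)
  nu <- make_gradient(chemotactic_spec("linear"), g)
  env <- compose_environment(nu, h, grid = g)
  jj <- matrix(1:32, 32, 32, byrow = TRUE)
  phi <- tanh((jj - 28) / sqrt(2))
  mask <- matrix(FALSE, 32, 32); mask[, 31:32] <- TRUE
  res <- reservoir_spec(mask, 1)
  p <- model_params(dt = 5e-3)
  sched <- units_to_hours(c(100, 200), g)
  base <- run_simulation(env, p, g, res, phase_state(phi), sched)
  null_deg <- run_simulation(env, p, g, res, phase_state(phi), sched,
                             degradation = degradation_params(power = 0,
                               cadence_steps = 5000L))
  for (k in seq_along(base$snapshots))
    expect_identical(base$snapshots[[k]], null_deg$snapshots[[k]])
})

test_that("the tip avoids the dense corridor of a fork", {
  # two corridors ahead of the tip: one clear, one dense; across seeded
  # noise realizations the sensing decision must always target the clear one
  g <- grid_spec(40L, 40L)
  nu <- make_gradient(chemotactic_spec("linear"), g)
  dp <- degradation_params(sensing_radius_px = 8, sigma_px = 3)
  tip <- structure(list(x = 20L, y = 28L), class = "tip_position")
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    h <- matrix(1, 40, 40)
    h[13:17, 12:28] <- 0                        # clear left corridor
    h[23:27, 12:28] <- 0.9                      # dense right corridor
    h <- pmin(pmax(h + matrix(rnorm(1600, 0, 0.05), 40, 40), 0), 1)
    env <- compose_environment(nu, scalar_field(h, "hydrogel_density"))
    dec <- sense_environment(env, tip, dp)
    if (dec$target_center[1] < 20) hits <- hits + 1L
  }
  expect_gte(hits, 9.5)  # >= 95% of seeds
})

test_that("degradation yields a straighter tip path than a meandering pore", {
  g <- grid_spec(48L, 48L, dx_um = 16, time_unit_h = 1.1e-2, dt = 5e-3)
  nu <- make_gradient(chemotactic_spec("linear"), g)
  jj <- matrix(1:48, 48, 48, byrow = TRUE)
  phi <- tanh((jj - 42) / sqrt(2))
  mask <- matrix(FALSE, 48, 48); mask[, 47:48] <- TRUE
  res <- reservoir_spec(mask, 1)
  p <- model_params(dt = 5e-3)
  # long enough that path structure dominates the +/- 1 px tip jitter
  sched <- units_to_hours(seq(800, 8800, by = 800), g)

  tortu <- function(traj) tip_tortuosity(tip_track(traj))
  set.seed(42)
  noise <- matrix(rnorm(48 * 48, 0, 0.03), 48, 48)

  # fundamental model forced through a meandering carved pore
  h_m <- matrix(1, 48, 48)
  h_m <- pmin(pmax(h_m + noise, 0), 1)
  meander <- path_spec(rbind(c(24, 48), c(12, 36), c(36, 20), c(24, 1)),
                       width_px = 7)
  env_m <- compose_environment(nu, carve_open_path(
    scalar_field(h_m, "hydrogel_density"), meander), grid = g)
  traj_m <- run_simulation(env_m, p, g, res, phase_state(phi), sched)

  # degradation model in the uncarved matrix
  env_d <- compose_environment(nu, scalar_field(h_m, "hydrogel_density"),
                               grid = g)
  traj_d <- run_simulation(env_d, p, g, res, phase_state(phi), sched,
                           degradation = degradation_params(
                             sensing_radius_px = 6, power = 0.4,
                             sigma_px = 3, cadence_steps = 2000L))
  expect_lte(tortu(traj_d), tortu(traj_m) + 1e-9)
})
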