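test_that("gradient profiles hit the canonical values", {
  g <- grid_spec()
  # uniform: every site at beta
  u <- make_gradient(chemotactic_spec("uniform", beta = 0.3), g)
  expect_true(all(u == 0.3))
  expect_error(chemotactic_spec("uniform", beta = 0.6), "0, 0.5")

  # linear 0.1 y + 0.3: 0.3 at the cell-side edge, 0.5 at the far edge,
  # exactly 0.4 at 100 px from the cell edge
  lin <- make_gradient(chemotactic_spec("linear", alpha = 0.1, beta = 0.3), g)
  expect_equal(lin[1, g$ny], 0.3)
  expect_equal(lin[1, 1], 0.5, tolerance = 1e-2)
  expect_equal(lin[57, g$ny - 100], 0.4)
  expect_true(all(lin >= 0 & lin <= 0.5))
  # constant across the transverse axis, affine along y
  expect_equal(lin[1, ], lin[g$nx, ])
  expect_equal(diff(diff(lin[1, ])), rep(0, g$ny - 2))

  z <- make_gradient(chemotactic_spec("zero"), g)
  expect_true(all(z == 0))

  pk <- make_gradient(chemotactic_spec("peaked", start_level = 0.1,
                                       peak_level = 0.5, peak_pos_px = 100), g)
  expect_equal(pk[1, g$ny], 0.1)
  expect_equal(max(pk), 0.5)
  expect_equal(pk[1, g$ny - 100], 0.5)  # the peak
  expect_lt(pk[1, 1], 0.01)             # decays to ~0 at the far edge
})

test_that("environment composition follows C0 = max(nu_c - gamma h, floor)", {
  # pointwise example: nu_c = 0.4, h = 1, gamma = 0.5 -> raw -0.1 -> clamped 0
  env <- compose_environment(scalar_field(matrix(0.4, 4, 4), "nu_c"),
                             scalar_field(matrix(1, 4, 4), "hydrogel_density"),
                             gamma = 0.5, floor = 0)
  expect_true(all(env$C0 == 0))
  expect_true(all(env$bands == "hydrogel"))

  # h == 0: C0 equals nu_c everywhere
  g <- grid_spec(16L, 16L)
  nu <- make_gradient(chemotactic_spec("linear"), g)
  env0 <- compose_environment(nu, scalar_field(matrix(0, 16, 16),
                                               "hydrogel_density"))
  expect_equal(field_values(env0$C0), field_values(nu))

  # canonical banding: dense matrix under the [0.3, 0.5] gradient is in the
  # hydrogel band; open pore is in the chemoattractant band
  set.seed(4)
  h <- matrix(sample(c(0, 1), 16 * 16, TRUE), 16, 16)
  env2 <- compose_environment(nu, scalar_field(h, "hydrogel_density"),
                              gamma = 0.5)
  expect_true(all(env2$C0[h == 1] <= 0.1))
  expect_true(all(env2$bands[h == 1] == "hydrogel"))
  expect_true(all(env2$C0[h == 0] >= 0.3 - 1e-9))
  expect_true(all(env2$bands[h == 0] == "chemo_pore"))

  expect_error(compose_environment(nu, scalar_field(matrix(0, 8, 8),
                                                    "hydrogel_density")),
               "shape mismatch")
})

test_that("composition identity and band partition hold on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    nu <- matrix(runif(400, 0, 0.5), 20, 20)
    h <- matrix(runif(400), 20, 20)
    gamma <- runif(1, 0.2, 1)
    env <- compose_environment(scalar_field(nu, "nu_c"),
                               scalar_field(h, "hydrogel_density"), gamma)
    C0 <- field_values(env$C0)
    uncl <- C0 > env$floor
    expect_equal(max(abs(C0[uncl] + gamma * h[uncl] - nu[uncl])), 0)
    expect_true(all(C0[!uncl] == env$floor))
    expect_true(all(env$bands %in% c("hydrogel", "interface", "chemo_pore")))
    expect_equal(length(env$bands), length(C0))
  }
})

test_that("band classification uses half-open boundaries and rejects C0 > 0.5", {
  expect_equal(classify_bands(matrix(0.05))[1, 1], "hydrogel")
  expect_equal(classify_bands(matrix(0.1))[1, 1], "interface")
  expect_equal(classify_bands(matrix(0.2))[1, 1], "chemo_pore")
  expect_equal(classify_bands(matrix(0.35))[1, 1], "chemo_pore")
  expect_equal(classify_bands(matrix(0.5))[1, 1], "chemo_pore")
  expect_error(classify_bands(matrix(0.51)), "exceeds 0.5")
})

test_that("synthetic ECM generator is deterministic and respects porosity", {
  g <- grid_spec(64L, 64L)
  spec <- ecm_gen_spec(porosity = 0.5, correlation_length_px = 3, seed = 11L)
  h1 <- generate_synthetic_ecm(spec, g)
  h2 <- generate_synthetic_ecm(spec, g)
  expect_identical(field_values(h1), field_values(h2))
  expect_equal(mean(h1 == 0), 0.5, tolerance = 0.02)

  # porosity -> 1 limit: essentially all pore
  sp2 <- ecm_gen_spec(porosity = 0.99, correlation_length_px = 3, seed = 1L)
  expect_lt(mean(field_values(generate_synthetic_ecm(sp2, g))), 0.02)

  # different seed, different field
  h3 <- generate_synthetic_ecm(ecm_gen_spec(0.5, 40, 3, seed = 12L), g)
  expect_false(identical(field_values(h1), field_values(h3)))
})

test_that("calibrated generator hits the target mean pore size", {
  g <- grid_spec()
  spec <- calibrate_ecm(ecm_gen_spec(porosity = 0.5, target_mean_pore_um = 40,
                                     seed = 5L), g)
  sizes <- vapply(1:6, function(s) {
    h <- generate_synthetic_ecm(ecm_gen_spec(0.5, 40, spec$correlation_length_px,
                                             seed = 100L + s), g)
    measure_mean_pore_size(h, grid = g)
  }, numeric(1))
  expect_equal(mean(sizes), 40, tolerance = 0.15)
  # out-of-range target errors out
  expect_error(calibrate_ecm(ecm_gen_spec(0.5, 1e5, NULL, 1L), g),
               "cannot calibrate")
})

test_that("carve_open_path zeroes the corridor and nothing else", {
  g <- grid_spec(40L, 40L)
  h <- scalar_field(matrix(1, 40, 40), "hydrogel_density")
  p <- path_spec(rbind(c(20, 1), c(20, 40)), width_px = 10)
  hc <- carve_open_path(h, p)
  expect_true(all(hc[20, ] == 0))
  expect_true(all(hc[16:25, ] == 0))       # inside corridor
  expect_true(all(hc[c(1:13, 27:40), ] == 1))  # >= width/2 + 1 px away

  # idempotent on pore space
  h0 <- scalar_field(matrix(0, 40, 40), "hydrogel_density")
  expect_equal(field_values(carve_open_path(h0, p)), field_values(h0))

  # L-shaped path against the brute-force corridor oracle
  wp <- rbind(c(10, 5), c(10, 30), c(32, 30))
  pl <- path_spec(wp, width_px = 6)
  hl <- carve_open_path(h, pl)
  oracle <- naive_in_corridor(40, 40, wp, 6)
  expect_equal(field_values(hl), matrix(as.numeric(!oracle), 40, 40))
  for (k in seq_len(nrow(wp))) expect_equal(hl[wp[k, 1], wp[k, 2]], 0)

  expect_error(path_spec(matrix(numeric(0), 0, 2)), "empty waypoint")
  expect_error(carve_open_path(h, path_spec(rbind(c(99, 1)), 4)),
               "outside grid")
})

test_that("image loader normalizes, resamples and warns on constant input", {
  g <- grid_spec(20L, 20L)
  tmp <- tempfile(fileext = ".csv")
  # pixel checkerboard of {0, 255}, 40 x 40, downsampled 2:1 -> all 0.5
  cb <- 255 * outer(1:40, 1:40, function(i, j) (i + j) %% 2)
  write.table(cb, tmp, sep = ",", row.names = FALSE, col.names = FALSE)
  f <- load_hydrogel_image(tmp, g)
  expect_equal(field_values(f), matrix(0.5, 20, 20))

  # shape contract: 400 x 400 input onto a 200 x 200 grid
  g200 <- grid_spec(200L, 200L)
  big <- tempfile(fileext = ".csv")
  set.seed(1)
  write.table(matrix(runif(400 * 400), 400, 400), big, sep = ",",
              row.names = FALSE, col.names = FALSE)
  fb <- load_hydrogel_image(big, g200)
  expect_equal(dim(fb), c(200L, 200L))

  # normalization invariance under affine intensity rescaling
  img <- matrix(runif(40 * 40), 40, 40)
  t1 <- tempfile(fileext = ".csv"); t2 <- tempfile(fileext = ".csv")
  write.table(img, t1, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(0.2 + 0.5 * img, t2, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_equal(field_values(load_hydrogel_image(t1, g)),
               field_values(load_hydrogel_image(t2, g)), tolerance = 1e-12)

  # constant image: warning + all-zero field
  tc <- tempfile(fileext = ".csv")
  write.table(matrix(255, 20, 20), tc, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_warning(fc <- load_hydrogel_image(tc, g), "zero-dynamic-range")
  expect_true(all(fc == 0))

  expect_error(load_hydrogel_image("no-such-file.pgm", g), "cannot read")
})

test_that("PGM/PPM text images parse and match their matrix equivalents", {
  g <- grid_spec(8L, 8L)
  vals <- matrix(sample(0:255, 64, TRUE), 8, 8)
  pgm <- tempfile(fileext = ".pgm")
  # netpbm row-major: rows are y (top first), columns are x
  writeLines(c("P2", "# comment", "8 8", "255",
               apply(t(vals), 1, paste, collapse = " ")), pgm)
  csv <- tempfile(fileext = ".csv")
  write.table(vals, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(field_values(load_hydrogel_image(pgm, g)),
               field_values(load_hydrogel_image(csv, g)), tolerance = 1e-12)

  # grayscale PPM (equal channels) matches the PGM
  ppm <- tempfile(fileext = ".ppm")
  rgbline <- function(row) paste(rep(row, each = 3), collapse = " ")
  writeLines(c("P3", "8 8", "255", apply(t(vals), 1, rgbline)), ppm)
  expect_equal(field_values(load_hydrogel_image(ppm, g)),
               field_values(load_hydrogel_image(pgm, g)), tolerance = 1e-12)
})
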