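# Phantom simulator: FEM ground truth, contrast calibration, scatterers
# and convolution RF synthesis.

test_that("homogeneous FEM reproduces the closed-form uniform strain", {
  # 0.6 mm on 20 mm with slip bottom and free sides: eps_yy = -3% exactly
  sp <- phantom_spec(incl_radius = 0, compression = 6e-4, mesh_n = 32)
  tr <- solve_fem(sp)
  expect_lt(max(abs(tr$strain - 0.03)) / 0.03, 0.01)
  # lateral expansion at plane strain: eps_xx = nu/(1-nu) * 3%
  ux_edge <- truth_displacement(tr, 0.010, 0.009)$ux
  expect_equal(ux_edge, 0.495 / (1 - 0.495) * 0.03 * 0.009,
               tolerance = 0.01)
  # displacement is the linear ramp compression * (1 - z/height)
  u_mid <- truth_displacement(tr, 0.010, 0)$uz
  expect_equal(u_mid, 3e-4, tolerance = 1e-6)
  u_bot <- truth_displacement(tr, 0.0199, 0)$uz
  expect_lt(abs(u_bot), 2e-5)
  # boundary conditions hold exactly at constrained nodes
  expect_true(all(tr$uy[1, ] == 6e-4))
  expect_true(all(tr$uy[nrow(tr$uy), ] == 0))
})

test_that("zero compression yields identically zero fields", {
  sp <- phantom_spec(incl_radius = 0, compression = 0, mesh_n = 16)
  tr <- solve_fem(sp)
  expect_true(all(tr$uy == 0) && all(tr$ux == 0))
  expect_true(all(tr$strain == 0))
})

test_that("mesh refinement leaves the contrast ratio stable", {
  r40 <- qselast:::truth_roi_ratio(
    solve_fem(phantom_spec(compression = 6e-4, mesh_n = 40)))
  r80 <- qselast:::truth_roi_ratio(
    solve_fem(phantom_spec(compression = 6e-4, mesh_n = 80)))
  expect_lt(abs(r40 - r80) / r80, 0.02)
})

test_that("contrast calibration hits the target and is monotone", {
  sp <- phantom_spec(compression = 6e-4, mesh_n = 40)
  expect_identical(calibrate_contrast(sp, 1), sp$E_inclusion)
  E5 <- calibrate_contrast(sp, 5)
  sp$E_background <- E5
  r <- qselast:::truth_roi_ratio(solve_fem(sp))
  expect_lt(abs(r - 5), 0.1)
  # a stiffer inclusion strains less than its background
  expect_lt(mean(solve_fem(sp)$strain[20:21, 20:21]),
            mean(solve_fem(sp)$strain[1:5, 1:5]))
  # softer background -> larger strain ratio (monotonicity of the search)
  soft <- sp; soft$E_background <- E5 / 2
  stiff <- sp; stiff$E_background <- E5 * 2
  expect_gt(qselast:::truth_roi_ratio(solve_fem(soft)),
            qselast:::truth_roi_ratio(solve_fem(stiff)))
})

test_that("scatterer fields are reproducible, Poisson-sized and independent", {
  sp <- phantom_spec(compression = 0, mesh_n = 16)
  ts <- transducer_spec()
  s1 <- make_scatterers(sp, ts, 101)
  s2 <- make_scatterers(sp, ts, 101)
  expect_identical(s1, s2)
  lambda <- ts$scatterer_density * sp$width * sp$height * 1e6
  expect_lt(abs(nrow(s1) - lambda), 3 * sqrt(lambda))
  # different seeds give uncorrelated rasterized fields
  s3 <- make_scatterers(sp, ts, 202)
  rast <- function(s) {
    h <- table(cut(s$z, seq(0, 0.02, length.out = 21)),
               cut(s$x, seq(-0.01, 0.01, length.out = 21)))
    as.vector(h)
  }
  expect_lt(abs(cor(rast(s1), rast(s3))), 0.2)
})

test_that("scatterers move with the FEM field", {
  sp <- phantom_spec(incl_radius = 0, compression = 6e-4, mesh_n = 32)
  tr <- solve_fem(sp)
  sc <- data.frame(x = c(0, 0, 0.005), z = c(0.010, 0.0199, 0.005),
                   amp = c(1, 1, 1))
  moved <- displace_scatterers(sc, tr)
  # mid-depth: compression * (1 - z/h) = 0.3 mm toward the fixed bottom
  expect_equal(moved$z[1] - sc$z[1], 3e-4, tolerance = 1e-6)
  # near the fixed bottom: essentially immobile
  expect_lt(abs(moved$z[2] - sc$z[2]), 2e-5)
  expect_identical(moved$amp, sc$amp)
  # zero compression leaves positions unchanged
  tr0 <- solve_fem(phantom_spec(incl_radius = 0, compression = 0,
                                mesh_n = 16))
  expect_equal(displace_scatterers(sc, tr0), sc, tolerance = 1e-12)
})

test_that("RF synthesis places echoes at the two-way travel time", {
  ts <- transducer_spec(n_lines = 8, line_spacing = 1e-3, depth = 0.010,
                        noise_snr = Inf)
  line_x <- (seq_len(8) - 4.5) * 1e-3
  one <- data.frame(x = line_x[4], z = 0.005, amp = 1)
  fr <- simulate_rf(one, ts, 1)
  env <- Mod(analytic_signal(fr)$values)
  expect_lte(abs(which.max(env[, 4]) -
                 (round(2 * 0.005 * ts$fs / ts$c) + 1)), 1)
  # off-axis lines see the echo attenuated by the beam profile
  expect_lt(max(env[, 8]), 0.05 * max(env[, 4]))
  # moving the scatterer shifts the echo by 2 dz fs / c samples
  dz <- 50e-6
  fr2 <- simulate_rf(data.frame(x = line_x[4], z = 0.005 + dz, amp = 1),
                     ts, 1)
  env2 <- Mod(analytic_signal(fr2)$values)
  expect_lte(abs(which.max(env2[, 4]) - which.max(env[, 4]) -
                 round(2 * dz * ts$fs / ts$c)), 1)
})

test_that("speckle frames have the transducer's spectral signature", {
  sp <- phantom_spec(incl_radius = 0, compression = 0, mesh_n = 16,
                     width = 0.010, height = 0.010,
                     incl_center = c(0.005, 0))
  ts <- transducer_spec(n_lines = 32, line_spacing = 0.010 / 32,
                        depth = 0.010)
  fr <- simulate_rf(make_scatterers(sp, ts, 5), ts, 6)
  P <- rowMeans(Mod(stats::mvfft(fr$samples))^2)
  f <- (seq_along(P) - 1) / length(P) * ts$fs
  pk <- f[which.max(P[f < ts$fs / 2])]
  expect_lt(abs(pk - ts$f0) / ts$f0, 0.10)
})

test_that("pairs are seed-deterministic and coherent", {
  cfg <- test_cfg_small()
  sp <- qselast:::cfg_phantom_spec(cfg, compression = 2e-4)
  ts <- qselast:::cfg_transducer_spec(cfg)
  p1 <- suppressWarnings(make_pair(sp, ts, 7))   # edge scatterers clip
  p2 <- suppressWarnings(make_pair(sp, ts, 7))
  expect_identical(p1$pre$samples, p2$pre$samples)
  expect_identical(p1$post$samples, p2$post$samples)
  # zero compression: frames identical up to the independent noise draws
  sp0 <- qselast:::cfg_phantom_spec(cfg, compression = 0)
  p0 <- make_pair(sp0, ts, 7)
  expect_gt(cor(as.vector(p0$pre$samples), as.vector(p0$post$samples)),
            0.95)
  expect_false(identical(p0$pre$samples, p0$post$samples))
})
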