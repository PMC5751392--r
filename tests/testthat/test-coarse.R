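# Coarse block matching: NCC, following tracking, the three search levels,
# lateral finalization and grid interpolation.

test_that("ncc matches the brute-force double-loop oracle to 1e-12", {
  set.seed(11)
  B <- matrix(rnorm(40 * 40), 40, 40)
  A <- B[13:28, 13:28] + 0.1 * rnorm(256)   # 16 x 16 window
  dys <- -2:2; dxs <- -2:2
  surf <- ncc(A, B, dys, dxs, anchor = c(13, 13))
  oracle <- ncc_oracle(A, B, dys, dxs, anchor = c(13, 13))
  expect_lt(max(abs(surf$values - oracle)), 1e-12)
  expect_true(all(surf$values >= -1 - 1e-12 & surf$values <= 1 + 1e-12))
})

test_that("ncc detects embedded shifts and flags zero-variance windows", {
  set.seed(12)
  A <- matrix(rnorm(100), 10, 10)
  B <- matrix(rnorm(30 * 30, sd = 0.01), 30, 30)
  B[14:23, 12:21] <- A                      # offset (3, 1) from anchor (11, 11)
  surf0 <- ncc(A, B, -5:5, -5:5, anchor = c(14, 12))
  am0 <- qselast:::surface_argmax(surf0)
  expect_equal(unname(am0[c("dy", "dx")]), c(0, 0))
  expect_equal(unname(am0["peak"]), 1, tolerance = 1e-12)
  surf <- ncc(A, B, -5:5, -5:5, anchor = c(11, 11))
  am <- qselast:::surface_argmax(surf)
  expect_equal(unname(am[c("dy", "dx")]), c(3, 1))
  expect_warning(s <- ncc(matrix(1, 4, 4), B, -1:1, -1:1,
                          anchor = c(11, 11)), "zero-variance")
  expect_true(all(is.nan(s$values)))
  expect_error(ncc(A, B, -20:0, 0, anchor = c(11, 11)), "cannot contain")
})

test_that("following tracking equals exhaustive argmax on unimodal surfaces", {
  surf_eval <- function(dy, dx) -((dy - 5)^2 + (dx + 3)^2)
  bounds <- list(dy = c(-10, 10), dx = c(-10, 10))
  tr <- following_track(surf_eval, c(0, 0), bounds)
  expect_equal(tr$point, c(5, -3))
  expect_equal(tr$status, "converged")
  # exhaustive oracle over the bounded region
  grid <- expand.grid(dy = -10:10, dx = -10:10)
  best <- grid[which.max(mapply(surf_eval, grid$dy, grid$dx)), ]
  expect_equal(tr$point, c(best$dy, best$dx))
  # random strictly unimodal surfaces: always the exhaustive argmax
  for (seed in 1:5) {
    set.seed(seed)
    pk <- c(sample(-6:6, 1), sample(-6:6, 1))
    f <- function(dy, dx) -1.3 * (dy - pk[1])^2 - 0.7 * (dx - pk[2])^2
    tr2 <- following_track(f, c(0, 0), bounds)
    expect_equal(tr2$point, pk)
  }
  # peak already at the start
  tr3 <- following_track(surf_eval, c(5, -3), bounds)
  expect_equal(tr3$steps, 0L)
  expect_equal(tr3$status, "converged")
  # maximum outside the search range
  tr4 <- following_track(surf_eval, c(0, 0), list(dy = c(-2, 2),
                                                  dx = c(-2, 2)))
  expect_equal(tr4$status, "hit_boundary")
  expect_error(following_track(surf_eval, c(9, 9),
                               list(dy = c(0, 2), dx = c(0, 2))),
               "outside bounds")
})

test_that("level 1 recovers no-deformation and global integer shifts", {
  env <- speckle_env(200, 60, seed = 21)
  spec <- search_spec(20, 10, 6, 4)
  g0 <- level1_search(env, env, spec)
  expect_true(all(g0$axial == 0) && all(g0$lateral == 0))
  expect_true(all(g0$valid))
  g4 <- level1_search(env, shift_mat(env, 4, 0), spec)
  expect_true(all(g4$axial == 4) && all(g4$lateral == 0))
  expect_error(level1_search(env[1:10, ], env[1:10, ], spec), "small")
})

test_that("levels 2 and 3 track a global shift from a coarse init", {
  cfg <- default_config()
  env <- speckle_env(400, 60, seed = 22)
  post <- shift_mat(env, 6, 1)
  init <- displacement_grid(matrix(3, 3, 3), matrix(1, 3, 3),
                            c(60, 200, 340), c(10, 30, 50))
  spec2 <- search_spec(13, 4, 10, 3)
  g2 <- level2_search(env, post, init, spec2, cfg, scale_axial = 2)
  inner <- 2:6   # rows away from the zero-fill frontier
  expect_true(all(g2$axial[inner, 2:10] == 6))
  expect_true(all(g2$lateral[inner, 2:10] == 1))
  spec3 <- search_spec(13, 4, 6, 2)
  g3 <- level3_search(env, post, g2, spec3, cfg, scale_axial = 1)
  mid <- g3$axial[10:(nrow(g3$axial) - 10), 3:(ncol(g3$axial) - 3)]
  expect_gt(mean(mid == 6), 0.95)
  # precondition on the level-1 grid
  bad <- init; bad$valid <- matrix(c(TRUE, rep(FALSE, 8)), 3, 3)
  expect_error(level2_search(env, post, bad, spec2, cfg), "fewer than 5")
})

test_that("the three levels agree on a global shift across the pyramid", {
  # speckle RF frame shifted by exactly 8 finest samples: levels at rates
  # 8/4/2 should report 1/2/4 of their own samples
  set.seed(23)
  n <- 1600
  t <- seq_len(n) - 1
  lines <- lapply(1:48, function(l)
    list(centers = sort(runif(220, -20, n + 20)), amps = rnorm(220)))
  mk <- function(delay) {
    cols <- vapply(lines, function(ln)
      pulse_train(t - delay, ln$centers, ln$amps), numeric(n))
    rf_frame(cols, fs = 120e6, f0 = 7.5e6, line_spacing = 1.5625e-4)
  }
  cfg <- default_config(n_lines = 48)
  pre <- qselast:::preprocess_frame(mk(0), cfg)
  post <- qselast:::preprocess_frame(mk(8), cfg)
  co <- qselast:::coarse_pipeline(pre$pyramid, post$pyramid, cfg)
  expect_equal(median(co$level1$axial), 1)
  expect_equal(median(co$level2$axial), 2)
  expect_equal(median(co$level3$axial), 4)
  expect_true(mean(co$level3$axial == 4) > 0.9)
  expect_true(all(abs(co$level3$lateral_final) <= 0.25))
})

test_that("lateral finalization preserves polynomials and gates small shifts", {
  centers_y <- seq(10, 100, by = 10); centers_x <- seq(5, 60, by = 5)
  const <- matrix(2, 10, 12)
  g <- displacement_grid(const * 0, const, centers_y, centers_x)
  out <- finalize_lateral(g, 9, 2, 0.25)
  expect_equal(out, const, tolerance = 1e-10)
  gz <- displacement_grid(const * 0, const * 0, centers_y, centers_x)
  expect_true(all(finalize_lateral(gz, 9, 2, 0.25) == 0))
  ramp <- matrix(seq(1, 3, length.out = 12), 10, 12, byrow = TRUE)
  gr <- displacement_grid(ramp * 0, ramp, centers_y, centers_x)
  out_r <- finalize_lateral(gr, 9, 2, 0.25)
  expect_equal(out_r[, 3:10], ramp[, 3:10], tolerance = 1e-10)
  # sub-threshold shifts are zeroed
  tiny <- matrix(0.1, 10, 12)
  gt <- displacement_grid(tiny * 0, tiny, centers_y, centers_x)
  expect_true(all(finalize_lateral(gt, 9, 2, 0.25) == 0))
  expect_error(finalize_lateral(g, 8, 2, 0.25), "odd")
})

test_that("grid interpolation rescales units and reproduces planes exactly", {
  cy <- c(10, 20, 30, 40); cx <- c(5, 15, 25, 35)
  plane <- outer(cy, cx, function(y, x) 2 * y + 3 * x)
  g <- displacement_grid(plane, plane / 2, cy, cx)
  # identity at the source centers
  id <- interp_grid(g, cy, cx)
  expect_equal(id$axial, plane, tolerance = 1e-12)
  # a bilinear plane is reproduced exactly at midpoints
  my <- c(15, 25, 35); mx <- c(10, 20, 30)
  mid <- interp_grid(g, my, mx)
  expect_equal(mid$axial, outer(my, mx, function(y, x) 2 * y + 3 * x),
               tolerance = 1e-12)
  # constant grids stay constant anywhere, with unit scaling applied
  gc <- displacement_grid(matrix(5, 4, 4), matrix(1, 4, 4), cy, cx)
  out <- interp_grid(gc, c(12, 38), c(7, 33), scale_axial = 2)
  expect_true(all(out$axial == 10) && all(out$lateral == 1))
  expect_error(interp_grid(displacement_grid(matrix(0, 0, 0),
                                             matrix(0, 0, 0),
                                             numeric(0), numeric(0)),
                           1, 1), "empty")
})
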