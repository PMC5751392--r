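# LSQSE strain reconstruction and the quality metrics.

test_that("LSQSE is exact on linear and constant displacement", {
  z <- seq_len(200)
  for (kernel in c(5, 21, 41)) {
    s <- lsqse_line(0.02 * z, z, kernel)
    expect_lt(max(abs(s - 0.02)), 1e-12)
    expect_lt(max(abs(lsqse_line(rep(3, 200), z, kernel))), 1e-12)
  }
  expect_error(lsqse_line(z, z, 4), "odd")
  expect_error(lsqse_line(z[1:10], z[1:10], 11), "exceeds")
})

test_that("LSQSE on noisy data matches per-window normal equations", {
  set.seed(41)
  n <- 2000; kernel <- 41; m <- 20
  z <- seq_len(n)
  u <- 0.01 * z + rnorm(n, sd = 0.1)
  s <- lsqse_line(u, z, kernel)
  expect_lt(abs(mean(s) - 0.01), 0.001)
  # independent closed-form least-squares slope per window
  oracle <- vapply(seq_along(s), function(j) {
    idx <- j:(j + kernel - 1)
    A <- cbind(z[idx], 1)
    ab <- solve(t(A) %*% A, t(A) %*% u[idx])
    ab[1]
  }, 0)
  expect_lt(max(abs(s - oracle)), 1e-10)
})

test_that("strain maps carry the compression-positive sign convention", {
  ctr <- seq(13, 600, by = 6)
  nl <- 8
  mk_field <- function(u) displacement_field(
    matrix(u, length(ctr), nl), matrix(0, length(ctr), nl), ctr,
    seq_len(nl), matrix(1L, length(ctr), nl),
    matrix(TRUE, length(ctr), nl))
  meta <- list(fs = 120e6, c = 1540, line_spacing = 1.5e-4, n_lines = nl)
  # compression: displacement decreases with depth -> positive strain
  mp <- strain_map(mk_field(-0.02 * ctr), 41, meta)
  expect_equal(mean(mp$strain), 0.02, tolerance = 1e-10)
  z0 <- strain_map(mk_field(0 * ctr), 41, meta)
  expect_true(all(abs(z0$strain) < 1e-12))
  expect_equal(nrow(mp$strain), length(ctr) - 40)
})

two_level_map <- function(lo = 0.01, hi = 0.05, n = 40) {
  # left half hi (background-like), right half lo
  s <- cbind(matrix(hi, n, n / 2), matrix(lo, n, n / 2))
  structure(list(strain = s, centers_axial = seq_len(n),
                 centers_lateral = seq_len(n),
                 meta = list(fs = 0.5, c = 1, line_spacing = 1,
                             n_lines = n)),
            class = "strain_map")
  # with these meta values pixel (i, j) sits at depth i, lateral j - (n+1)/2
}

test_that("CNRe reproduces direct arithmetic and its invariances", {
  n <- 40
  map <- two_level_map(n = n)
  set.seed(42)
  noise <- matrix(rnorm(n * n, sd = 0.003), n, n)
  map$strain <- map$strain + noise
  roi_inc <- roi_spec("rectangle", c(20, 12), half_extents = c(6, 6),
                      role = "inclusion")
  roi_bg <- roi_spec("rectangle", c(20, -12), half_extents = c(6, 6),
                     role = "background")
  v <- cnre(map, roi_inc, roi_bg)
  s1 <- map$strain[qselast:::roi_mask(map, roi_inc)]
  s2 <- map$strain[qselast:::roi_mask(map, roi_bg)]
  expect_equal(v, 2 * (mean(s1) - mean(s2))^2 / (var(s1) + var(s2)),
               tolerance = 1e-12)
  # the two-mean / two-variance arithmetic on constructed pixels:
  # means 2 and 1, variances 0.25 each -> CNRe = 4
  d <- 0.5 * sqrt((length(s1) - 1) / length(s1))
  map2 <- map
  map2$strain[qselast:::roi_mask(map, roi_inc)] <-
    rep(c(2 - d, 2 + d), length.out = length(s1))
  map2$strain[qselast:::roi_mask(map, roi_bg)] <-
    rep(c(1 - d, 1 + d), length.out = length(s2))
  expect_equal(cnre(map2, roi_inc, roi_bg), 2 * 1 / 0.5, tolerance = 1e-6)
  # identical ROI statistics give 0
  map3 <- map; map3$strain[] <- rep(c(0.01, 0.03), length.out = n * n)
  expect_equal(cnre(map3, roi_inc, roi_bg), 0, tolerance = 1e-20)
  # affine invariance: strain -> a * strain + b
  map_af <- map; map_af$strain <- -3.7 * map$strain + 0.2
  expect_equal(cnre(map_af, roi_inc, roi_bg), v, tolerance = 1e-9)
  # zero total variance -> Inf with a warning
  mapc <- map; mapc$strain[] <- rep(c(1, 2), each = n * n / 2)
  expect_warning(vc <- cnre(mapc, roi_inc, roi_bg), "Inf")
  expect_identical(vc, Inf)
  # tiny ROI is refused
  expect_error(cnre(map, roi_spec("circle", c(20, 12), radius = 1,
                                  role = "inclusion"), roi_bg), "pixels")
})

test_that("strain ratio reads the configured contrast orientation", {
  map <- two_level_map(lo = 0.01, hi = 0.05)
  roi_inc <- roi_spec("rectangle", c(20, 12), half_extents = c(6, 6),
                      role = "inclusion")
  roi_bg <- roi_spec("rectangle", c(20, -12), half_extents = c(6, 6),
                     role = "background")
  expect_equal(strain_ratio(map, roi_inc, roi_bg), 5, tolerance = 1e-12)
  mapu <- map; mapu$strain[] <- 0.03
  expect_equal(strain_ratio(mapu, roi_inc, roi_bg), 1)
  mapz <- map; mapz$strain[qselast:::roi_mask(map, roi_inc)] <- 0
  expect_warning(r <- strain_ratio(mapz, roi_inc, roi_bg), "Inf")
  expect_identical(r, Inf)
})

test_that("binarization is mean-thresholded, idempotent, and counts area", {
  map <- two_level_map(lo = 0.01, hi = 0.05)
  b <- binarize(map)
  expect_true(all(b[, 21:40]) && !any(b[, 1:20]))
  expect_equal(inclusion_area_ratio(b), 0.5)
  # uniform map: nothing strictly below the mean
  mapu <- map; mapu$strain[] <- 0.02
  expect_true(all(!binarize(mapu)))
  expect_equal(inclusion_area_ratio(binarize(mapu)), 0)
  # recomputing the threshold on the same map changes nothing
  expect_identical(binarize(map), binarize(map))
  expect_error(inclusion_area_ratio(logical(0)), "empty")
  mapn <- map; mapn$strain[1, 1] <- NaN
  expect_error(binarize(mapn), "finite")
})

test_that("the FEM-truth strain map carries the configured contrast and geometry", {
  spec <- phantom_spec(compression = 6e-4, mesh_n = 48)
  truth <- solve_fem(spec)
  map <- truth_strain_map(truth)
  rois <- qselast:::default_rois(default_config(mesh_n = 48))
  # configured contrast 5 within 15%
  r <- strain_ratio(map, rois$inclusion, rois$background)
  expect_lt(abs(r - 5) / 5, 0.15)
  # inclusion strains less than the background
  expect_lt(mean(map$strain[qselast:::roi_mask(map, rois$inclusion)]),
            mean(map$strain[qselast:::roi_mask(map, rois$background)]))
  # mean-thresholding paints the whole inclusion black, and the black blob
  # containing the inclusion center covers the inclusion disk.  (Under
  # displacement-controlled compression the columns above and below the
  # stiff inclusion strain harder, and the far-field background straddles
  # the whole-map mean, so the black area exceeds the geometric
  # pi r^2 / (w h) reference; the study reports the ratio as computed.)
  b <- binarize(map)
  CY <- matrix(truth$cy, 48, 48)
  CX <- matrix(truth$cx, 48, 48, byrow = TRUE)
  incl <- (CY - spec$incl_center[1])^2 + (CX - spec$incl_center[2])^2 <=
    (0.9 * spec$incl_radius)^2
  expect_true(all(b[incl]))
  ctr <- c(which.min(abs(truth$cy - spec$incl_center[1])),
           which.min(abs(truth$cx - spec$incl_center[2])))
  blob <- b & FALSE
  # flood fill from the center within the black mask
  reach <- function(mask, row, col) {
    lab <- matrix(FALSE, nrow(mask), ncol(mask))
    q <- list(c(row, col)); lab[row, col] <- TRUE
    while (length(q)) {
      p <- q[[1]]; q <- q[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- p + d
        if (r[1] >= 1 && r[1] <= nrow(mask) && r[2] >= 1 &&
            r[2] <= ncol(mask) && mask[r[1], r[2]] && !lab[r[1], r[2]]) {
          lab[r[1], r[2]] <- TRUE
          q[[length(q) + 1]] <- r
        }
      }
    }
    lab
  }
  blob <- reach(b, ctr[1], ctr[2])
  expect_true(all(blob[incl]))
  geom <- pi * 0.003^2 / (0.02 * 0.02)
  expect_gt(inclusion_area_ratio(b), geom)
})
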