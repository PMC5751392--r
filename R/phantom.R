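# Inclusion-phantom simulator: plane-strain linear-elastic FEM for the
# ground-truth displacement/strain fields, random scatterer fields, and a
# separable convolution PSF model (Gaussian-enveloped axial pulse x
# Gaussian lateral beam) for RF synthesis.
#
# Coordinates: x lateral (centered on the aperture), y = depth, increasing
# downward from the top (transducer) surface.  Positive axial displacement
# is motion toward greater depth; the top surface is pushed down by
# `compression` against a fixed bottom.

#' Phantom specification
#'
#' A `width` x `height` rectangular block with a circular inclusion,
#' uniaxially compressed from the top against a fixed bottom.
#'
#' @param width,height block extents, m.
#' @param incl_center `(depth, lateral)` inclusion center, m.
#' @param incl_radius inclusion radius, m (0 = homogeneous block).
#' @param E_inclusion,E_background Young's moduli, Pa.
#' @param poisson Poisson's ratio, strictly below 0.5.
#' @param density material density, kg/m^3 (carried as metadata).
#' @param compression applied top-surface axial displacement, m
#'   (must stay below 10% of `height`).
#' @param mesh_n FEM elements per side.
#' @param bottom_bc `"slip"` (axially fixed, lateral free) or `"clamped"`.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(width = 0.020, height = 0.020,
                         incl_center = c(0.010, 0), incl_radius = 0.003,
                         E_inclusion = 1e5, E_background = 1.293e4,
                         poisson = 0.495, density = 1000,
                         compression = 6e-4, mesh_n = 80,
                         bottom_bc = c("slip", "clamped")) {
  bottom_bc <- match.arg(bottom_bc)
  if (poisson <= 0 || poisson >= 0.5)
    stop("phantom_spec: poisson must be in (0, 0.5)", call. = FALSE)
  if (compression < 0 || compression >= 0.1 * height)
    stop("phantom_spec: compression must be in [0, 0.1 * height)",
         call. = FALSE)
  if (incl_radius > 0) {
    if (incl_center[1] - incl_radius < 0 ||
        incl_center[1] + incl_radius > height ||
        abs(incl_center[2]) + incl_radius > width / 2)
      stop("phantom_spec: inclusion must lie fully inside the block",
           call. = FALSE)
  }
  structure(list(width = width, height = height, incl_center = incl_center,
                 incl_radius = incl_radius, E_inclusion = E_inclusion,
                 E_background = E_background, poisson = poisson,
                 density = density, compression = compression,
                 mesh_n = as.integer(mesh_n), bottom_bc = bottom_bc),
            class = "phantom_spec")
}

#' Transducer / acquisition specification
#'
#' @param f0 center frequency, Hz.  @param fs RF sampling frequency, Hz.
#' @param n_lines scan lines.  @param line_spacing lateral pitch, m.
#' @param c sound speed, m/s.  @param pulse_bw -6 dB fractional bandwidth.
#' @param beam_sigma lateral Gaussian beam sigma, m.
#' @param scatterer_density expected scatterers per mm^2.
#' @param noise_snr additive white noise SNR, dB.
#' @param depth imaged depth extent, m.
#' @return a `transducer_spec`.
#' @export
transducer_spec <- function(f0 = 7.5e6, fs = 120e6, n_lines = 128,
                            line_spacing = 0.020 / 128, c = 1540,
                            pulse_bw = 0.6, beam_sigma = 4e-4,
                            scatterer_density = 20, noise_snr = 30,
                            depth = 0.020) {
  if (fs <= 2 * f0)
    stop("transducer_spec: fs must exceed 2 * f0", call. = FALSE)
  structure(list(f0 = f0, fs = fs, n_lines = as.integer(n_lines),
                 line_spacing = line_spacing, c = c, pulse_bw = pulse_bw,
                 beam_sigma = beam_sigma,
                 scatterer_density = scatterer_density,
                 noise_snr = noise_snr, depth = depth),
            class = "transducer_spec")
}

# specs from a run configuration
cfg_phantom_spec <- function(cfg, compression = cfg$compression,
                             homogeneous = FALSE) {
  phantom_spec(width = cfg$width, height = cfg$height,
               incl_center = c(cfg$incl_cz, cfg$incl_cx),
               incl_radius = if (homogeneous) 0 else cfg$incl_radius,
               E_inclusion = cfg$E_inclusion,
               E_background = if (homogeneous) cfg$E_inclusion else
                 cfg$E_background,
               poisson = cfg$poisson, density = cfg$density,
               compression = compression, mesh_n = cfg$mesh_n,
               bottom_bc = cfg$bottom_bc)
}

cfg_transducer_spec <- function(cfg) {
  transducer_spec(f0 = cfg$f0, fs = cfg$fs, n_lines = cfg$n_lines,
                  line_spacing = cfg_line_spacing(cfg), c = cfg$c,
                  pulse_bw = cfg$pulse_bw, beam_sigma = cfg$beam_sigma,
                  scatterer_density = cfg$scatterer_density,
                  noise_snr = cfg$noise_snr, depth = cfg$height)
}

# 8x8 plane-strain Q4 stiffness for E = 1 on an hx x hy element, with
# selective reduced integration: the shear/deviatoric (mu) term uses 2x2
# Gauss, the volumetric (lambda) term one central point, which prevents
# volumetric locking at Poisson ratios near 0.5.
q4_stiffness <- function(hx, hy, nu) {
  mu <- 1 / (2 * (1 + nu))
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  D_mu <- mu * diag(c(2, 2, 1))
  D_lam <- lam * matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3)
  Bmat <- function(xi, eta) {
    # local nodes: (-1,-1), (1,-1), (1,1), (-1,1)
    dN_dxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dN_deta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    dN_dx <- dN_dxi * 2 / hx
    dN_dy <- dN_deta * 2 / hy
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dN_dx
    B[2, seq(2, 8, 2)] <- dN_dy
    B[3, seq(1, 8, 2)] <- dN_dy
    B[3, seq(2, 8, 2)] <- dN_dx
    B
  }
  g <- 1 / sqrt(3)
  K <- matrix(0, 8, 8)
  for (xi in c(-g, g)) for (eta in c(-g, g)) {
    B <- Bmat(xi, eta)
    K <- K + t(B) %*% D_mu %*% B * (hx * hy / 4)
  }
  B0 <- Bmat(0, 0)
  K <- K + t(B0) %*% D_lam %*% B0 * (hx * hy)
  list(K = K, B0 = B0, D_mu = D_mu, D_lam = D_lam)
}

#' Solve the plane-strain phantom for ground-truth fields
#'
#' Two-dimensional plane-strain linear elasticity on a regular bilinear
#' quadrilateral mesh with selective reduced integration of the volumetric
#' term (near-incompressibility at Poisson 0.495).  Boundary conditions:
#' top edge pushed down by `compression` with lateral slip free, bottom
#' edge axially fixed (`"slip"`: lateral free with one node pinned;
#' `"clamped"`: fully fixed), sides traction-free.
#'
#' @param spec a [phantom_spec()].
#' @return a `ground_truth` object holding nodal displacement grids, the
#'   element-centroid axial strain grid (compression reported positive) and
#'   the mesh coordinates; query it with [truth_displacement()] and
#'   [truth_strain()].
#' @export
solve_fem <- function(spec) {
  n <- spec$mesh_n
  nn <- n + 1L
  hx <- spec$width / n
  hy <- spec$height / n
  xs <- seq(-spec$width / 2, spec$width / 2, length.out = nn)
  ys <- seq(0, spec$height, length.out = nn)
  ke <- q4_stiffness(hx, hy, spec$poisson)

  # element material by centroid
  cxs <- (xs[-nn] + xs[-1]) / 2
  cys <- (ys[-nn] + ys[-1]) / 2
  CX <- matrix(cxs, n, n, byrow = TRUE)   # rows = y index, cols = x index
  CY <- matrix(cys, n, n)
  inside <- if (spec$incl_radius > 0) {
    (CY - spec$incl_center[1])^2 + (CX - spec$incl_center[2])^2 <=
      spec$incl_radius^2
  } else matrix(FALSE, n, n)
  E_el <- ifelse(inside, spec$E_inclusion, spec$E_background)

  # connectivity: node id (i = y index, j = x index) -> (j-1)*nn + i
  nid <- function(i, j) (j - 1L) * nn + i
  ei <- rep(seq_len(n), times = n)       # element y index
  ej <- rep(seq_len(n), each = n)        # element x index
  n1 <- nid(ei, ej); n2 <- nid(ei, ej + 1L)
  n3 <- nid(ei + 1L, ej + 1L); n4 <- nid(ei + 1L, ej)
  # local node order (-1,-1),(1,-1),(1,1),(-1,1) with xi ~ x, eta ~ y
  conn <- cbind(n1, n2, n3, n4)
  edof <- matrix(0L, n * n, 8)
  edof[, seq(1, 8, 2)] <- 2L * conn - 1L  # ux
  edof[, seq(2, 8, 2)] <- 2L * conn       # uy

  ii <- edof[, rep(seq_len(8), times = 8)]
  jj <- edof[, rep(seq_len(8), each = 8)]
  xx <- outer(as.vector(E_el), as.vector(ke$K))
  ndof <- 2L * nn * nn
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(xx), dims = c(ndof, ndof))

  # constraints
  top_nodes <- nid(1L, seq_len(nn))
  bot_nodes <- nid(nn, seq_len(nn))
  fixed <- c(2L * top_nodes, 2L * bot_nodes)            # uy dofs
  vals <- c(rep(spec$compression, nn), rep(0, nn))
  if (spec$bottom_bc == "clamped") {
    fixed <- c(fixed, 2L * bot_nodes - 1L)
    vals <- c(vals, rep(0, nn))
  } else {
    pin <- bot_nodes[ceiling(nn / 2)]                   # remove rigid motion
    fixed <- c(fixed, 2L * pin - 1L)
    vals <- c(vals, 0)
  }
  free <- setdiff(seq_len(ndof), fixed)
  if (length(free) == 0 || length(fixed) == 0)
    stop("solve_fem: degenerate constraint set", call. = FALSE)

  u <- numeric(ndof)
  u[fixed] <- vals
  if (spec$compression == 0) {
    # zero Dirichlet data everywhere: the solution is identically zero
    u[] <- 0
  } else {
    rhs <- -K[free, fixed, drop = FALSE] %*% u[fixed]
    u[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  }

  UX <- matrix(u[seq(1, ndof, 2)], nn, nn)   # rows = y, cols = x
  UY <- matrix(u[seq(2, ndof, 2)], nn, nn)

  # element-centroid axial strain eps_yy via the central B matrix
  ue <- cbind(u[2L * conn[, 1] - 1L], u[2L * conn[, 1]],
              u[2L * conn[, 2] - 1L], u[2L * conn[, 2]],
              u[2L * conn[, 3] - 1L], u[2L * conn[, 3]],
              u[2L * conn[, 4] - 1L], u[2L * conn[, 4]])
  eps_yy <- ue %*% ke$B0[2, ]
  strain <- matrix(-as.numeric(eps_yy), n, n)  # compression positive

  structure(list(x_nodes = xs, y_nodes = ys, ux = UX, uy = UY,
                 cx = cxs, cy = cys, strain = strain, spec = spec),
            class = "ground_truth")
}

#' @exportS3Method base::print
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d x %d mesh, compression %.3f mm (%.2f%%)\n",
              x$spec$mesh_n, x$spec$mesh_n, x$spec$compression * 1e3,
              100 * x$spec$compression / x$spec$height))
  cat(sprintf("  mean axial strain %.4f%%\n", 100 * mean(x$strain)))
  invisible(x)
}

#' Interpolate the ground-truth displacement field
#'
#' @param truth a `ground_truth` from [solve_fem()].
#' @param z,x depth and lateral query coordinates, m (vectors of equal
#'   length, or a grid via `grid = TRUE`).
#' @param grid if `TRUE`, return matrices over the tensor grid `z` x `x`.
#' @return list with `uz` and `ux` displacement components, m (lab frame:
#'   positive `uz` is motion toward the fixed bottom).
#' @export
truth_displacement <- function(truth, z, x, grid = FALSE) {
  if (grid) {
    list(uz = bilinear_interp(truth$y_nodes, truth$x_nodes, truth$uy, z, x),
         ux = bilinear_interp(truth$y_nodes, truth$x_nodes, truth$ux, z, x))
  } else {
    uz <- ux <- numeric(length(z))
    for (k in seq_along(z)) {
      uz[k] <- bilinear_interp(truth$y_nodes, truth$x_nodes, truth$uy,
                               z[k], x[k])[1, 1]
      ux[k] <- bilinear_interp(truth$y_nodes, truth$x_nodes, truth$ux,
                               z[k], x[k])[1, 1]
    }
    list(uz = uz, ux = ux)
  }
}

#' Interpolate the ground-truth axial strain field
#'
#' @inheritParams truth_displacement
#' @return matrix (grid) or vector of axial strain, compression positive.
#' @export
truth_strain <- function(truth, z, x, grid = FALSE) {
  if (grid) {
    bilinear_interp(truth$cy, truth$cx, truth$strain, z, x)
  } else {
    out <- numeric(length(z))
    for (k in seq_along(z))
      out[k] <- bilinear_interp(truth$cy, truth$cx, truth$strain,
                                z[k], x[k])[1, 1]
    out
  }
}

# background/inclusion mean strain ratio of a truth field, measured on the
# same circular ROIs the imaging metrics use
truth_roi_ratio <- function(truth, roi_radius = 1.5e-3,
                            bg_offset = 6.5e-3) {
  spec <- truth$spec
  CX <- matrix(truth$cx, length(truth$cy), length(truth$cx),
               byrow = TRUE)
  CY <- matrix(truth$cy, length(truth$cy), length(truth$cx))
  inc <- (CY - spec$incl_center[1])^2 + (CX - spec$incl_center[2])^2 <=
    roi_radius^2
  bgc <- c(spec$incl_center[1], spec$incl_center[2] + bg_offset)
  bg <- (CY - bgc[1])^2 + (CX - bgc[2])^2 <= roi_radius^2
  mean(truth$strain[bg]) / mean(truth$strain[inc])
}

#' Calibrate the background modulus to a target strain contrast
#'
#' One-dimensional root search over `E_background` (inclusion modulus held
#' fixed) until the FEM background/inclusion mean strain ratio — measured
#' on the default metric ROIs — is within 2% of `target_ratio`.
#'
#' @param spec a [phantom_spec()].
#' @param target_ratio desired background/inclusion strain ratio (> 1; a
#'   target of exactly 1 returns `E_inclusion`).
#' @param roi_radius,bg_offset ROI geometry, m.
#' @return the calibrated `E_background`, Pa.
#' @export
calibrate_contrast <- function(spec, target_ratio, roi_radius = 1.5e-3,
                               bg_offset = 6.5e-3) {
  if (target_ratio == 1) return(spec$E_inclusion)
  if (target_ratio < 1)
    stop("calibrate_contrast: target_ratio must be >= 1", call. = FALSE)
  if (spec$compression == 0) spec$compression <- 0.02 * spec$height
  ratio_at <- function(logE) {
    s <- spec; s$E_background <- 10^logE
    truth_roi_ratio(solve_fem(s), roi_radius, bg_offset) - target_ratio
  }
  lo <- log10(spec$E_inclusion) - 2.2
  hi <- log10(spec$E_inclusion) - 0.01
  flo <- ratio_at(lo); fhi <- ratio_at(hi)
  if (flo * fhi > 0)
    stop(sprintf(
      "calibrate_contrast: target %.2f not bracketed (ratio %.2f..%.2f over E_bg %.3g..%.3g Pa)",
      target_ratio, fhi + target_ratio, flo + target_ratio, 10^lo, 10^hi),
      call. = FALSE)
  root <- stats::uniroot(ratio_at, c(lo, hi), tol = 1e-4)
  E_bg <- 10^root$root
  achieved <- root$f.root + target_ratio
  if (abs(achieved - target_ratio) > 0.02 * target_ratio)
    warning(sprintf(
      "calibrate_contrast: achieved ratio %.3f misses target %.3f by > 2%%",
      achieved, target_ratio), call. = FALSE)
  E_bg
}

# RNG-preserving local seed
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a random scatterer field
#'
#' Scatterer count is Poisson with mean `density x area`; positions are
#' uniform over the block, amplitudes standard normal.  Reproducible from
#' `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param tspec a [transducer_spec()] (supplies the density).
#' @param seed integer seed.
#' @return data.frame with `x`, `z` (m, lab frame) and `amp`.
#' @export
make_scatterers <- function(spec, tspec, seed) {
  area_mm2 <- spec$width * spec$height * 1e6
  with_seed(seed, {
    nsc <- stats::rpois(1, tspec$scatterer_density * area_mm2)
    data.frame(
      x = stats::runif(nsc, -spec$width / 2, spec$width / 2),
      z = stats::runif(nsc, 0, spec$height),
      amp = stats::rnorm(nsc))
  })
}

#' Displace scatterers by the ground-truth field
#'
#' Each scatterer moves by the interpolated FEM displacement at its
#' position; amplitudes are unchanged.  Scatterers pushed outside the
#' domain (a numerical edge case) are clipped to the boundary with a
#' warning.
#'
#' @param scatterers data.frame from [make_scatterers()].
#' @param truth a `ground_truth` from [solve_fem()].
#' @return data.frame of displaced scatterers (lab frame).
#' @export
displace_scatterers <- function(scatterers, truth) {
  u <- truth_displacement(truth, scatterers$z, scatterers$x)
  z2 <- scatterers$z + u$uz
  x2 <- scatterers$x + u$ux
  spec <- truth$spec
  out_of <- z2 < 0 | z2 > spec$height |
    x2 < -spec$width / 2 | x2 > spec$width / 2
  if (any(out_of)) {
    warning(sprintf(
      "displace_scatterers: %d scatterer(s) clipped to the domain boundary",
      sum(out_of)), call. = FALSE)
    z2 <- pmin(pmax(z2, 0), spec$height)
    x2 <- pmin(pmax(x2, -spec$width / 2), spec$width / 2)
  }
  data.frame(x = x2, z = z2, amp = scatterers$amp)
}

# -6 dB fractional bandwidth -> Gaussian envelope sigma in seconds
pulse_sigma_t <- function(f0, pulse_bw) {
  sigma_f <- (pulse_bw * f0 / 2) / sqrt(2 * log(2))
  1 / (2 * pi * sigma_f)
}

#' Synthesize one RF frame from a scatterer field
#'
#' Convolution model: every scatterer contributes its amplitude times a
#' Gaussian lateral beam weight times a Gaussian-enveloped carrier pulse
#' centered at its two-way travel time, sampled at `fs`; independent white
#' Gaussian noise is added at `noise_snr`.
#'
#' @param scatterers data.frame with `x`, `z` (m, lab frame), `amp`.
#' @param tspec a [transducer_spec()].
#' @param seed integer seed (noise draw).
#' @param depth_origin depth of the transducer face in lab coordinates, m;
#'   the post-compression frame is imaged with the probe advanced by the
#'   applied compression (it rides the compressed surface).
#' @return an [rf_frame()].
#' @export
simulate_rf <- function(scatterers, tspec, seed, depth_origin = 0) {
  n_samples <- max(64L, ceiling(2 * tspec$depth * tspec$fs / tspec$c))
  line_x <- (seq_len(tspec$n_lines) - (tspec$n_lines + 1) / 2) *
    tspec$line_spacing
  sigma_t <- pulse_sigma_t(tspec$f0, tspec$pulse_bw)
  rf <- simulate_lines_cpp(scatterers$x, scatterers$z - depth_origin,
                           scatterers$amp, line_x,
                           tspec$fs, tspec$f0, tspec$c, sigma_t,
                           tspec$beam_sigma, n_samples)
  rms <- sqrt(mean(rf^2))
  if (rms > 0 && is.finite(tspec$noise_snr)) {
    sd_n <- rms * 10^(-tspec$noise_snr / 20)
    rf <- rf + with_seed(seed,
      matrix(stats::rnorm(length(rf), sd = sd_n), nrow(rf), ncol(rf)))
  }
  rf_frame(rf, fs = tspec$fs, f0 = tspec$f0, c = tspec$c,
           line_spacing = tspec$line_spacing)
}

#' Simulate a matched pre/post-compression RF pair with ground truth
#'
#' One call produces the pre-compression frame, the post-compression frame
#' (same speckle realization, scatterers moved by the FEM field and imaged
#' with the probe riding the compressed surface) and the FEM ground truth.
#' This is the fixture generator for the estimator comparison study.
#'
#' @param spec a [phantom_spec()].
#' @param tspec a [transducer_spec()].
#' @param seed integer seed; scatterer and the two (independent) noise
#'   draws are derived from it deterministically.
#' @param truth optional precomputed `ground_truth` for `spec` (saves the
#'   FEM solve when generating several speckle realizations of one phantom).
#' @return list of class `rf_pair`: `pre`, `post` ([rf_frame()]s), `truth`
#'   (`ground_truth`), `spec`, `tspec`, `seed`.
#' @export
make_pair <- function(spec, tspec, seed, truth = NULL) {
  sub <- with_seed(seed, sample.int(2^30, 3))
  scat <- make_scatterers(spec, tspec, sub[1])
  if (is.null(truth)) truth <- solve_fem(spec)
  scat2 <- displace_scatterers(scat, truth)
  pre <- simulate_rf(scat, tspec, sub[2], depth_origin = 0)
  post <- simulate_rf(scat2, tspec, sub[3],
                      depth_origin = spec$compression)
  structure(list(pre = pre, post = post, truth = truth, spec = spec,
                 tspec = tspec, seed = seed),
            class = "rf_pair")
}

#' Measured axial displacement implied by the ground truth
#'
#' The displacement the estimators should recover, in finest-rate samples
#' on the pre-frame grid: the probe rides the compressed surface, so a
#' material point at probe-frame depth `z` moves by `uz(z) - compression`
#' (negative: echoes arrive earlier, with magnitude growing toward the
#' fixed bottom).
#'
#' @param truth a `ground_truth`.
#' @param tspec a [transducer_spec()].
#' @param z depth coordinates, m.  @param x lateral coordinates, m.
#' @param grid tensor-grid query as in [truth_displacement()].
#' @return displacement in samples (and, for `grid = TRUE`, a matrix).
#' @export
truth_sample_shift <- function(truth, tspec, z, x, grid = FALSE) {
  u <- truth_displacement(truth, z, x, grid = grid)
  (u$uz - truth$spec$compression) * 2 * tspec$fs / tspec$c
}
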