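# Coarse displacement estimation: three-level block matching on the
# envelope pyramid.  Level 1 is a 3x3 exhaustive search at the coarsest
# rate; levels 2 and 3 refine by greedy "following tracking" of the
# correlation surface with a per-column delivering strategy; the lateral
# component is Savitzky-Golay smoothed and thresholded before the fine
# stage.
#
# Units: axial displacements are in that level's (decimated) samples,
# lateral displacements in scan lines at every level.

#' Search specification for one coarse level
#'
#' @param calc_h,calc_w calculation-window height (samples at the level's
#'   rate) and width (lines); both >= 4.
#' @param search_h,search_w half-ranges of the search region (samples,
#'   lines); both >= 1.
#' @param depth_growth additive growth of `search_h` per window row (the
#'   search region is enlarged in deeper rows where displacement has
#'   accumulated).
#' @return a `search_spec`.
#' @export
search_spec <- function(calc_h, calc_w, search_h, search_w,
                        depth_growth = 0.5) {
  if (calc_h < 4 || calc_w < 4)
    stop("search_spec: calculation window must be at least 4 x 4",
         call. = FALSE)
  if (search_h < 1 || search_w < 1)
    stop("search_spec: search half-ranges must be >= 1", call. = FALSE)
  structure(list(calc_h = as.integer(calc_h), calc_w = as.integer(calc_w),
                 search_h = as.integer(search_h),
                 search_w = as.integer(search_w),
                 depth_growth = depth_growth),
            class = "search_spec")
}

#' Sparse displacement grid
#'
#' @param axial,lateral real matrices of displacement estimates (samples at
#'   the grid's scale; lines).
#' @param centers_axial,centers_lateral strictly increasing window-center
#'   coordinates (1-based samples / lines).
#' @param valid logical matrix; `peak` optional peak correlations.
#' @return a `displacement_grid`.
#' @export
displacement_grid <- function(axial, lateral, centers_axial, centers_lateral,
                              valid = NULL, peak = NULL) {
  dm <- dim(axial)
  if (!identical(dim(lateral), dm))
    stop("displacement_grid: axial/lateral shape mismatch", call. = FALSE)
  if (length(centers_axial) != dm[1] || length(centers_lateral) != dm[2])
    stop("displacement_grid: center coordinates do not match grid shape",
         call. = FALSE)
  if (any(diff(centers_axial) <= 0) || any(diff(centers_lateral) <= 0))
    stop("displacement_grid: centers must be strictly increasing",
         call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, dm[1], dm[2])
  if (!identical(dim(valid), dm))
    stop("displacement_grid: valid shape mismatch", call. = FALSE)
  structure(list(axial = axial, lateral = lateral,
                 centers_axial = centers_axial,
                 centers_lateral = centers_lateral,
                 valid = valid, peak = peak),
            class = "displacement_grid")
}

#' @exportS3Method base::print
print.displacement_grid <- function(x, ...) {
  cat(sprintf("<displacement_grid> %d x %d windows, %.1f%% valid\n",
              nrow(x$axial), ncol(x$axial), 100 * mean(x$valid)))
  cat(sprintf("  axial range [%.2f, %.2f] samples, lateral [%.2f, %.2f] lines\n",
              min(x$axial), max(x$axial), min(x$lateral), max(x$lateral)))
  invisible(x)
}

#' Zero-normalized cross-correlation surface
#'
#' Evaluates the 2-D ZNCC of `A_window` against the equally sized patch of
#' `B_region` at every requested `(dy, dx)` offset.  Offset `(0, 0)` places
#' the window's top-left corner at `anchor` (1-based row, col) in
#' `B_region`.
#'
#' @param A_window real matrix (the pre-compression calculation window).
#' @param B_region real matrix containing every candidate patch.
#' @param offsets_axial,offsets_lateral integer offset vectors.
#' @param anchor 1-based (row, col) of the zero-offset patch in `B_region`.
#' @return a `correlation_surface`: `values` in `[-1, 1]` (NaN where a patch
#'   has zero variance), plus the offset grids.
#' @export
ncc <- function(A_window, B_region, offsets_axial, offsets_lateral,
                anchor = c(1L, 1L)) {
  if (anchor[1] + min(offsets_axial) < 1 ||
      anchor[2] + min(offsets_lateral) < 1 ||
      anchor[1] + max(offsets_axial) + nrow(A_window) - 1 > nrow(B_region) ||
      anchor[2] + max(offsets_lateral) + ncol(A_window) - 1 > ncol(B_region))
    stop("ncc: B_region cannot contain A_window at every requested offset",
         call. = FALSE)
  if (stats::var(as.vector(A_window)) == 0)
    warning("ncc: zero-variance calculation window, surface is all NaN",
            call. = FALSE)
  vals <- ncc_surface_cpp(A_window, B_region,
                          as.integer(anchor[1] - 1L),
                          as.integer(anchor[2] - 1L),
                          as.integer(offsets_axial),
                          as.integer(offsets_lateral))
  structure(list(values = vals,
                 offsets_axial = as.integer(offsets_axial),
                 offsets_lateral = as.integer(offsets_lateral)),
            class = "correlation_surface")
}

# deterministic argmax of a correlation surface: highest value wins, ties
# broken by smallest offset magnitude, then smallest dy, then smallest dx
surface_argmax <- function(surface) {
  v <- surface$values
  if (all(is.na(v))) return(NULL)
  best <- which(v == max(v, na.rm = TRUE), arr.ind = TRUE)
  dy <- surface$offsets_axial[best[, 1]]
  dx <- surface$offsets_lateral[best[, 2]]
  ord <- order(dy^2 + dx^2, dy, dx)
  c(dy = dy[ord[1]], dx = dx[ord[1]],
    peak = v[best[ord[1], 1], best[ord[1], 2]])
}

#' Greedy hill-climbing of a correlation surface ("following tracking")
#'
#' Starting from `init`, the reference point repeatedly moves to the
#' best-correlated point among itself and its stencil neighbourhood.
#' Terminates when the current point is the best (converged), when the best
#' neighbour leaves `bounds` (hit_boundary), or after `max_steps`.
#'
#' @param surface_eval function(dy, dx) returning a correlation value (may
#'   return NA outside its domain).
#' @param init integer `(dy, dx)` starting point, inside `bounds`.
#' @param bounds list with `dy = c(lo, hi)`, `dx = c(lo, hi)`.
#' @param neighborhood two-column integer matrix of stencil offsets
#'   (default: full 5x5 minus the center).
#' @param max_steps step cap.
#' @return a `track_result`: `point` (dy, dx), `status` one of
#'   `"converged"`, `"hit_boundary"`, `"max_steps"`, and `steps`.
#' @export
following_track <- function(surface_eval, init, bounds,
                            neighborhood = NULL, max_steps = 50) {
  if (is.null(neighborhood)) {
    g <- expand.grid(dy = -2:2, dx = -2:2)
    neighborhood <- as.matrix(g[!(g$dy == 0 & g$dx == 0), ])
  }
  if (init[1] < bounds$dy[1] || init[1] > bounds$dy[2] ||
      init[2] < bounds$dx[1] || init[2] > bounds$dx[2])
    stop("following_track: init outside bounds", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(dy, dx) {
    key <- paste(dy, dx)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- surface_eval(dy, dx)
    cache[[key]] <- if (is.null(v) || is.na(v)) NA_real_ else v
    cache[[key]]
  }
  cur <- as.integer(init)
  cur_v <- eval_at(cur[1], cur[2])
  steps <- 0L
  status <- "max_steps"
  while (steps <= max_steps) {
    cand_dy <- cur[1] + neighborhood[, 1]
    cand_dx <- cur[2] + neighborhood[, 2]
    vals <- mapply(eval_at, cand_dy, cand_dx)
    pool_dy <- c(cur[1], cand_dy)
    pool_dx <- c(cur[2], cand_dx)
    pool_v <- c(cur_v, vals)
    keep <- !is.na(pool_v)
    if (!any(keep)) { status <- "converged"; break }
    ord <- order(-pool_v[keep], pool_dy[keep]^2 + pool_dx[keep]^2,
                 pool_dy[keep], pool_dx[keep])
    bi <- which(keep)[ord[1]]
    if (pool_dy[bi] == cur[1] && pool_dx[bi] == cur[2]) {
      status <- "converged"; break
    }
    if (pool_dy[bi] < bounds$dy[1] || pool_dy[bi] > bounds$dy[2] ||
        pool_dx[bi] < bounds$dx[1] || pool_dx[bi] > bounds$dx[2]) {
      status <- "hit_boundary"; break
    }
    cur <- unname(c(pool_dy[bi], pool_dx[bi]))
    cur_v <- pool_v[bi]
    steps <- steps + 1L
    if (steps >= max_steps) { status <- "max_steps"; break }
  }
  structure(list(point = cur, status = status, steps = steps,
                 peak = cur_v),
            class = "track_result")
}

# replace invalid grid entries by the median of their valid 8-neighbours
# (falling back to the global valid median)
fill_invalid <- function(axial, lateral, valid) {
  if (all(valid)) return(list(axial = axial, lateral = lateral))
  if (!any(valid)) return(list(axial = axial * 0, lateral = lateral * 0))
  idx <- which(!valid, arr.ind = TRUE)
  nr <- nrow(axial); nc <- ncol(axial)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ri <- max(1, i - 1):min(nr, i + 1)
    rj <- max(1, j - 1):min(nc, j + 1)
    nb <- valid[ri, rj, drop = FALSE]
    if (any(nb)) {
      axial[i, j] <- stats::median(axial[ri, rj][nb])
      lateral[i, j] <- stats::median(lateral[ri, rj][nb])
    } else {
      axial[i, j] <- stats::median(axial[valid])
      lateral[i, j] <- stats::median(lateral[valid])
    }
  }
  list(axial = axial, lateral = lateral)
}

# clamp an offset range so the shifted patch stays inside the post frame
clamp_offsets <- function(lo, hi, top, extent, frame_extent) {
  lo <- max(lo, 1L - top)
  hi <- min(hi, frame_extent - extent - top + 1L)
  if (lo > hi) NULL else seq.int(lo, hi)
}

#' Level-1 coarse search
#'
#' Nine evenly distributed windows (3x3 grid at axial/lateral fractions
#' 1/6, 1/2, 5/6 of the coarsest-scale frame); each window's displacement is
#' the argmax of a full exhaustive NCC surface.  The axial search half-range
#' grows with window row by `depth_growth` per row.  Windows whose peak
#' correlation falls below `corr_floor` are marked invalid and filled by the
#' median of their valid neighbours.
#'
#' @param pre_env,post_env coarsest-scale envelope matrices.
#' @param spec a [search_spec()].
#' @param corr_floor validity floor on peak NCC.
#' @return a 3x3 [displacement_grid()] (units: coarsest-scale samples,
#'   lines).
#' @export
level1_search <- function(pre_env, post_env, spec, corr_floor = 0.3) {
  H <- nrow(pre_env); W <- ncol(pre_env)
  h <- spec$calc_h; w <- spec$calc_w
  max_sh <- ceiling(spec$search_h * (1 + 2 * spec$depth_growth))
  need_h <- h + 2 * max_sh + 2
  need_w <- w + 2 * spec$search_w + 2
  if (H < h + 2 || W < w + 2)
    stop(sprintf(
      "level1_search: frame %d x %d too small for 3x3 layout (needs >= %d x %d)",
      H, W, need_h, need_w), call. = FALSE)
  cy <- round(H * c(1 / 6, 1 / 2, 5 / 6))
  cx <- round(W * c(1 / 6, 1 / 2, 5 / 6))
  cy <- pmin(pmax(cy, floor(h / 2) + 1), H - ceiling(h / 2))
  cx <- pmin(pmax(cx, floor(w / 2) + 1), W - ceiling(w / 2))
  axial <- lateral <- peak <- matrix(0, 3, 3)
  valid <- matrix(FALSE, 3, 3)
  for (i in 1:3) {
    sh <- ceiling(spec$search_h * (1 + spec$depth_growth * (i - 1)))
    for (j in 1:3) {
      top <- cy[i] - floor(h / 2); left <- cx[j] - floor(w / 2)
      A <- pre_env[top:(top + h - 1), left:(left + w - 1)]
      dys <- clamp_offsets(-sh, sh, top, h, H)
      dxs <- clamp_offsets(-spec$search_w, spec$search_w, left, w, W)
      if (is.null(dys) || is.null(dxs))
        stop("level1_search: search region does not fit in the frame",
             call. = FALSE)
      surf <- suppressWarnings(
        ncc(A, post_env, dys, dxs, anchor = c(top, left)))
      am <- surface_argmax(surf)
      if (!is.null(am)) {
        axial[i, j] <- am["dy"]; lateral[i, j] <- am["dx"]
        peak[i, j] <- am["peak"]
        valid[i, j] <- is.finite(am["peak"]) && am["peak"] >= corr_floor
      }
    }
  }
  filled <- fill_invalid(axial, lateral, valid)
  displacement_grid(filled$axial, filled$lateral, cy, cx, valid, peak)
}

# shared driver for levels 2 and 3: interpolate the init grid to the target
# centers, run the compiled following-track with delivering, fill invalid
track_level <- function(pre_env, post_env, init_grid, spec, cy, cx,
                        scale_axial, bound_h, bound_w, cfg) {
  init_ax <- bilinear_interp(init_grid$centers_axial * scale_axial,
                             init_grid$centers_lateral,
                             init_grid$axial * scale_axial, cy, cx)
  init_lat <- bilinear_interp(init_grid$centers_axial * scale_axial,
                              init_grid$centers_lateral,
                              init_grid$lateral, cy, cx)
  res <- track_grid_cpp(pre_env, post_env,
                        as.integer(cy - 1L), as.integer(cx - 1L),
                        spec$calc_h, spec$calc_w,
                        init_ax, init_lat,
                        as.integer(bound_h), as.integer(bound_w),
                        as.integer(cfg$track_max_steps),
                        as.integer(cfg$stencil_half), TRUE)
  valid <- is.finite(res$peak) & res$peak >= cfg$corr_floor
  filled <- fill_invalid(res$axial, res$lateral, valid)
  g <- displacement_grid(filled$axial, filled$lateral, cy, cx, valid,
                         res$peak)
  g$steps <- res$steps
  g$status <- res$status
  g
}

#' Level-2 coarse search
#'
#' 7 x 11 evenly distributed calculation windows at the mid scale.  The
#' level-1 grid is rescaled to mid-scale sample units and bilinearly
#' interpolated to the window centers; each window is then refined by
#' following tracking, and within each column the result of a window seeds
#' the initial reference point of the next window below it (the delivering
#' strategy).
#'
#' @param pre_env,post_env mid-scale envelope matrices.
#' @param init_grid the level-1 [displacement_grid()].
#' @param spec a [search_spec()] at the mid scale.
#' @param cfg a [default_config()]; supplies tracking bounds and the
#'   validity floor.
#' @param scale_axial axial sample-unit ratio between level-1 and level-2
#'   rates (e.g. 2 for rates 8 -> 4).
#' @return a 7 x 11 [displacement_grid()] in mid-scale units.
#' @export
level2_search <- function(pre_env, post_env, init_grid, spec,
                          cfg = default_config(), scale_axial = 2) {
  if (sum(init_grid$valid) < 5)
    stop("level2_search: level-1 grid valid on fewer than 5 of 9 windows",
         call. = FALSE)
  H <- nrow(pre_env); W <- ncol(pre_env)
  my <- ceiling(spec$calc_h / 2) + 1L
  mx <- ceiling(spec$calc_w / 2) + 1L
  if (H <= 2 * my || W <= 2 * mx)
    stop("level2_search: frame too small for the 7 x 11 layout",
         call. = FALSE)
  cy <- round(seq(my, H - my, length.out = 7))
  cx <- round(seq(mx, W - mx, length.out = 11))
  track_level(pre_env, post_env, init_grid, spec, cy, cx, scale_axial,
              cfg$l2_bound_h, cfg$l2_bound_w, cfg)
}

#' Level-3 coarse search
#'
#' Calculation windows half the level-2 size tile the whole frame at the
#' configured overlap; the same tracking and delivering strategy is used.
#'
#' @inheritParams level2_search
#' @param overlap window overlap fraction in both axes.
#' @return a [displacement_grid()] covering the whole frame (level-3 sample
#'   units, lines).
#' @export
level3_search <- function(pre_env, post_env, init_grid, spec,
                          cfg = default_config(), scale_axial = 2,
                          overlap = cfg$l3_overlap) {
  H <- nrow(pre_env); W <- ncol(pre_env)
  my <- ceiling(spec$calc_h / 2) + 1L
  mx <- ceiling(spec$calc_w / 2) + 1L
  step_y <- max(1L, round(spec$calc_h * (1 - overlap)))
  step_x <- max(1L, round(spec$calc_w * (1 - overlap)))
  cy <- seq.int(my, H - my, by = step_y)
  cx <- seq.int(mx, W - mx, by = step_x)
  track_level(pre_env, post_env, init_grid, spec, cy, cx, scale_axial,
              cfg$l3_bound_h, cfg$l3_bound_w, cfg)
}

#' Finalize the lateral displacement field
#'
#' Smooths the lateral component of a coarse grid along the lateral
#' direction with a Savitzky-Golay filter, then zeroes entries whose
#' smoothed magnitude falls below `significance_threshold`: only the
#' significant part of the lateral field is used to shift the
#' post-compression RF lines.
#'
#' @param grid a [displacement_grid()].
#' @param sg_window odd Savitzky-Golay window length (> `sg_order`).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param significance_threshold lines; smoothed magnitudes below this are
#'   set to 0.
#' @return lateral displacement matrix (lines), same shape as the grid.
#' @export
finalize_lateral <- function(grid, sg_window = 9, sg_order = 2,
                             significance_threshold = 0.25) {
  if (sg_window %% 2 == 0 || sg_window <= sg_order)
    stop("finalize_lateral: sg_window must be odd and exceed sg_order",
         call. = FALSE)
  lat <- grid$lateral
  if (ncol(lat) >= sg_window) {
    lat <- t(apply(lat, 1, function(row)
      signal::sgolayfilt(row, p = sg_order, n = sg_window)))
  }
  lat[abs(lat) < significance_threshold] <- 0
  lat
}

# bilinear interpolation from values Z on grid (src_y, src_x) to the
# cartesian product of (ty, tx); nearest-value extrapolation at the edges
bilinear_interp <- function(src_y, src_x, Z, ty, tx) {
  ny <- length(src_y); nx <- length(src_x)
  iy <- findInterval(ty, src_y, all.inside = TRUE)
  ix <- findInterval(tx, src_x, all.inside = TRUE)
  fy <- (ty - src_y[iy]) / (src_y[iy + 1] - src_y[iy])
  fx <- (tx - src_x[ix]) / (src_x[ix + 1] - src_x[ix])
  fy <- pmin(pmax(fy, 0), 1)   # clamp = nearest extrapolation
  fx <- pmin(pmax(fx, 0), 1)
  if (ny == 1) { iy <- rep(1L, length(ty)); fy <- rep(0, length(ty)) }
  if (nx == 1) { ix <- rep(1L, length(tx)); fx <- rep(0, length(tx)) }
  Z11 <- Z[iy, ix, drop = FALSE]
  Z21 <- Z[pmin(iy + 1, ny), ix, drop = FALSE]
  Z12 <- Z[iy, pmin(ix + 1, nx), drop = FALSE]
  Z22 <- Z[pmin(iy + 1, ny), pmin(ix + 1, nx), drop = FALSE]
  Fy <- matrix(fy, length(ty), length(tx))
  Fx <- matrix(fx, length(ty), length(tx), byrow = TRUE)
  Z11 * (1 - Fy) * (1 - Fx) + Z21 * Fy * (1 - Fx) +
    Z12 * (1 - Fy) * Fx + Z22 * Fy * Fx
}

#' Rescale and interpolate a displacement grid
#'
#' Multiplies both components by the sample-unit scale ratios between
#' pyramid levels, then bilinearly interpolates onto the target center
#' grid (nearest-value extrapolation outside the source hull).
#'
#' @param grid a [displacement_grid()].
#' @param target_centers_axial,target_centers_lateral target coordinates in
#'   the *target* scale's units.
#' @param scale_axial,scale_lateral unit ratios applied to values and to the
#'   source center coordinates.
#' @return a [displacement_grid()] on the target centers.
#' @export
interp_grid <- function(grid, target_centers_axial, target_centers_lateral,
                        scale_axial = 1, scale_lateral = 1) {
  if (length(grid$axial) == 0)
    stop("interp_grid: empty grid", call. = FALSE)
  sy <- grid$centers_axial * scale_axial
  sx <- grid$centers_lateral * scale_lateral
  ax <- bilinear_interp(sy, sx, grid$axial * scale_axial,
                        target_centers_axial, target_centers_lateral)
  lat <- bilinear_interp(sy, sx, grid$lateral * scale_lateral,
                         target_centers_axial, target_centers_lateral)
  displacement_grid(ax, lat, target_centers_axial, target_centers_lateral)
}

# full coarse pipeline: pyramids in, fine-stage initialization out
coarse_pipeline <- function(pre_pyr, post_pyr, cfg) {
  t0 <- proc.time()[3]
  rates <- vapply(pre_pyr$levels, `[[`, 0L, "rate")
  env <- function(pyr, k) pyr$levels[[k]]$envelope
  lam <- cfg$fs / cfg$f0                      # carrier wavelength, samples
  r1 <- rates[1]; r2 <- rates[2]; r3 <- rates[3]
  H1 <- nrow(env(pre_pyr, 1))

  calc_h1 <- max(4L, round(cfg$l1_win_wavelengths * lam / r1))
  calc_w1 <- max(4L, cfg$l1_win_lines)
  sh1 <- max(2L, ceiling(1.5 * cfg$expected_max_strain * H1 / 3))
  sw1 <- max(3L, ceiling(1.5 * cfg$expected_max_strain * cfg$n_lines / 2))
  spec1 <- search_spec(calc_h1, calc_w1, sh1, sw1)
  g1 <- level1_search(env(pre_pyr, 1), env(post_pyr, 1), spec1,
                      cfg$corr_floor)

  calc_h2 <- max(4L, round(calc_h1 * (r1 / r2) / 3))
  calc_w2 <- max(4L, round(calc_w1 / 3))
  spec2 <- search_spec(calc_h2, calc_w2, cfg$l2_bound_h, cfg$l2_bound_w)
  g2 <- level2_search(env(pre_pyr, 2), env(post_pyr, 2), g1, spec2, cfg,
                      scale_axial = r1 / r2)

  calc_h3 <- max(4L, round(calc_h2 * (r2 / r3) / 2))
  calc_w3 <- max(4L, round(calc_w2 / 2))
  spec3 <- search_spec(calc_h3, calc_w3, cfg$l3_bound_h, cfg$l3_bound_w)
  g3 <- level3_search(env(pre_pyr, 3), env(post_pyr, 3), g2, spec3, cfg,
                      scale_axial = r2 / r3)

  lat3 <- finalize_lateral(g3, cfg$sg_window, cfg$sg_order,
                           cfg$lateral_sig_threshold)
  g3$lateral_final <- lat3
  qse_log("coarse", "levels 1-3 done (%d x %d level-3 windows) in %.2fs",
          nrow(g3$axial), ncol(g3$axial), proc.time()[3] - t0)
  list(level1 = g1, level2 = g2, level3 = g3, rate3 = r3)
}
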