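# Fine (sub-sample) axial displacement estimation by phase zero-crossing
# Newton iteration on the complex baseband.  Three variants:
#   * fine_field_modified    - per-window coarse initialization plus lateral
#                              line shift of the post frame (the 2D hybrid)
#   * fine_field_chained_1d  - the original 1D scheme: each window inherits
#                              the previous window's estimate along the line
#   * fine_field_downsampled_1d - the chained scheme on decimated baseband
#
# Lags are in finest-rate samples, positive when the post-frame echo
# arrives later (motion toward greater depth).

#' Phase zero-crossing configuration
#'
#' @param window_T fine window length, samples.
#' @param overlap window overlap fraction in `[0, 1)`.
#' @param w0 carrier angular frequency in rad/sample (i.e.
#'   `2 * pi * f0 / fs` at the data's rate).
#' @param max_iter Newton iteration cap (>= 1).
#' @param tol convergence tolerance on the lag update, samples (> 0).
#' @param init_mode `"coarse"` or `"chained"`.
#' @return a `phase_zero_config`.
#' @export
phase_zero_config <- function(window_T = 25, overlap = 0.75,
                              w0 = 2 * pi * 7.5e6 / 120e6,
                              max_iter = 20, tol = 1e-3,
                              init_mode = c("coarse", "chained")) {
  init_mode <- match.arg(init_mode)
  if (overlap < 0 || overlap >= 1)
    stop("phase_zero_config: overlap must be in [0, 1)", call. = FALSE)
  if (tol <= 0) stop("phase_zero_config: tol must be > 0", call. = FALSE)
  if (max_iter < 1)
    stop("phase_zero_config: max_iter must be >= 1", call. = FALSE)
  structure(list(window_T = as.integer(window_T), overlap = overlap,
                 w0 = w0, max_iter = as.integer(max_iter), tol = tol,
                 init_mode = init_mode),
            class = "phase_zero_config")
}

# window-center sample indices (1-based) tiling a line of length n
fine_centers <- function(n, T, overlap) {
  step <- max(1L, round(T * (1 - overlap)))
  lo <- floor(T / 2) + 1L
  hi <- n - T + floor(T / 2) + 1L
  if (hi < lo) stop("fine_centers: line shorter than one window",
                    call. = FALSE)
  seq.int(lo, hi, by = step)
}

#' Single-window phase zero-crossing lag estimate
#'
#' Newton iteration
#' `tau <- tau - arg(exp(1i w0 tau) * sum_t Conj(x1(t)) x2(t + tau)) / w0`
#' on a baseband window of length `T = length(x1_win)`, with `x2` evaluated
#' at non-integer lags by complex linear interpolation.  Converges to the
#' true lag only when the initialization error is within half a carrier
#' period (`pi / w0` samples); beyond that the iteration lands on a
#' phase-wrapped alias.
#'
#' @param x1_win complex baseband window (pre-compression).
#' @param x2_line complex baseband line (post-compression) covering the
#'   window at the lags visited.
#' @param init_tau initial lag, samples.
#' @param cfg a [phase_zero_config()].
#' @param t0 1-based start index of the window within its line.
#' @return list `tau` (samples), `iters`, `converged`.  If the window
#'   slides past the line the lag is clamped and `converged` is `FALSE`.
#' @export
phase_zero_window <- function(x1_win, x2_line, init_tau, cfg, t0 = 1L) {
  res <- phase_zero_window_cpp(as.complex(x1_win), as.complex(x2_line),
                               as.integer(t0 - 1L), as.numeric(init_tau),
                               cfg$w0, cfg$tol, cfg$max_iter)
  res
}

#' Dense displacement field container
#'
#' @param axial,lateral displacement matrices (finest-rate samples; lines),
#'   one row per fine window, one column per scan line.
#' @param centers_axial,centers_lateral window centers (samples, lines).
#' @param iterations integer matrix of Newton iteration counts.
#' @param converged logical matrix.
#' @return a `displacement_field`.
#' @export
displacement_field <- function(axial, lateral, centers_axial,
                               centers_lateral, iterations, converged) {
  dm <- dim(axial)
  stopifnot(identical(dim(lateral), dm), identical(dim(iterations), dm),
            identical(dim(converged), dm), all(iterations >= 0))
  structure(list(axial = axial, lateral = lateral,
                 centers_axial = centers_axial,
                 centers_lateral = centers_lateral,
                 iterations = iterations, converged = converged),
            class = "displacement_field")
}

#' @exportS3Method base::print
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d x %d windows, %.1f%% converged, mean %.1f iters\n",
    nrow(x$axial), ncol(x$axial), 100 * mean(x$converged),
    mean(x$iterations)))
  invisible(x)
}

# replace unconverged entries by the 3x3 median of converged neighbours
median_fill_field <- function(axial, converged) {
  if (all(converged)) return(axial)
  idx <- which(!converged, arr.ind = TRUE)
  nr <- nrow(axial); nc <- ncol(axial)
  out <- axial
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ri <- max(1, i - 1):min(nr, i + 1)
    rj <- max(1, j - 1):min(nc, j + 1)
    nb <- converged[ri, rj, drop = FALSE]
    if (any(nb)) out[i, j] <- stats::median(axial[ri, rj][nb])
  }
  out
}

#' Modified fine estimation (coarse-initialized, laterally shifted)
#'
#' For every fine window the post-compression line is first substituted by
#' the line at `line + round(lateral displacement)`; the window's Newton
#' iteration starts from the coarse axial estimate at its center and runs
#' independently of every other window.
#'
#' @param pre_bb,post_bb complex baseband matrices at the finest rate.
#' @param coarse_axial matrix of coarse axial initializations at the fine
#'   window centers (finest-rate samples), shape windows x lines.
#' @param final_lateral matrix of lateral displacements (lines), same shape.
#' @param cfg a [phase_zero_config()] with `init_mode = "coarse"`.
#' @return a [displacement_field()]; unconverged windows are flagged and
#'   replaced by the 3x3 median of converged neighbours.
#' @export
fine_field_modified <- function(pre_bb, post_bb, coarse_axial,
                                final_lateral, cfg) {
  if (cfg$init_mode != "coarse")
    stop("fine_field_modified: cfg$init_mode must be 'coarse'",
         call. = FALSE)
  centers <- fine_centers(nrow(pre_bb), cfg$window_T, cfg$overlap)
  nl <- ncol(pre_bb)
  stopifnot(identical(dim(coarse_axial), c(length(centers), nl)),
            identical(dim(final_lateral), c(length(centers), nl)))
  shift <- matrix(as.integer(round(final_lateral)), length(centers), nl)
  t0 <- proc.time()[3]
  res <- phase_zero_field_cpp(pre_bb, post_bb, as.integer(centers),
                              cfg$window_T, coarse_axial, shift,
                              cfg$w0, cfg$tol, cfg$max_iter, FALSE)
  # the iteration is only trustworthy within its capture range: a window
  # that lands more than half a carrier period from its coarse
  # initialization has slipped to a phase-wrapped alias and is treated
  # like an unconverged window
  slipped <- abs(res$tau - coarse_axial) > pi / cfg$w0
  res$converged[slipped] <- FALSE
  ax <- median_fill_field(res$tau, res$converged)
  qse_log("fine", "modified field %d x %d in %.2fs",
          length(centers), nl, proc.time()[3] - t0)
  displacement_field(ax, final_lateral, centers, seq_len(nl),
                     res$iters, res$converged)
}

#' Original chained 1D fine estimation
#'
#' Windows are processed top to bottom along each line; window `k` starts
#' from window `k - 1`'s estimate (the first window starts at 0).  No
#' lateral compensation: this is the conventional 1D phase zero-crossing
#' elastography baseline.
#'
#' @inheritParams fine_field_modified
#' @param cfg a [phase_zero_config()] with `init_mode = "chained"`.
#' @return a [displacement_field()].
#' @export
fine_field_chained_1d <- function(pre_bb, post_bb, cfg) {
  if (cfg$init_mode != "chained")
    stop("fine_field_chained_1d: cfg$init_mode must be 'chained'",
         call. = FALSE)
  centers <- fine_centers(nrow(pre_bb), cfg$window_T, cfg$overlap)
  nl <- ncol(pre_bb)
  zero_r <- matrix(0, length(centers), nl)
  zero_i <- matrix(0L, length(centers), nl)
  t0 <- proc.time()[3]
  res <- phase_zero_field_cpp(pre_bb, post_bb, as.integer(centers),
                              cfg$window_T, zero_r, zero_i,
                              cfg$w0, cfg$tol, cfg$max_iter, TRUE)
  ax <- median_fill_field(res$tau, res$converged)
  qse_log("fine", "chained-1D field %d x %d in %.2fs",
          length(centers), nl, proc.time()[3] - t0)
  f <- displacement_field(ax, zero_r, centers, seq_len(nl),
                          res$iters, res$converged)
  attr(f, "n_windows") <- length(centers) * nl
  f
}

#' Downsampled chained 1D fine estimation
#'
#' The second baseline: the frames are demodulated, anti-alias filtered and
#' axially decimated by `rate`, the chained 1D estimator runs on the
#' decimated baseband (with the carrier frequency and window length rescaled
#' accordingly), and the lags and window centers are converted back to
#' finest-rate sample units.
#'
#' @param pre,post [rf_frame()] objects.
#' @param rate integer decimation factor; must satisfy the pyramid's
#'   Nyquist contract.
#' @param cfg a [phase_zero_config()] with `init_mode = "chained"`.
#' @param fir_taps anti-alias FIR order.
#' @return a [displacement_field()] in finest-rate units, with attribute
#'   `n_windows` (window evaluations actually run).
#' @export
fine_field_downsampled_1d <- function(pre, post, rate, cfg, fir_taps = 64) {
  rate <- as.integer(rate)
  pyr_rates <- if (rate > 1L) c(rate, 1L) else 1L
  pp <- build_pyramid(demodulate(analytic_signal(pre)), pyr_rates,
                      fir_taps = fir_taps)
  qp <- build_pyramid(demodulate(analytic_signal(post)), pyr_rates,
                      fir_taps = fir_taps)
  bb1 <- pp$levels[[1]]$baseband
  bb2 <- qp$levels[[1]]$baseband
  # the configured window length and overlap apply to the decimated axis:
  # each window spans rate-times the physical extent and the line carries
  # 1/rate as many windows (the computational saving of this baseline)
  cfg_ds <- phase_zero_config(
    window_T = cfg$window_T, overlap = cfg$overlap, w0 = cfg$w0 * rate,
    max_iter = cfg$max_iter, tol = cfg$tol / rate,
    init_mode = "chained")
  f <- fine_field_chained_1d(bb1, bb2, cfg_ds)
  out <- displacement_field(f$axial * rate, f$lateral,
                            (f$centers_axial - 1) * rate + 1,
                            f$centers_lateral, f$iterations, f$converged)
  attr(out, "n_windows") <- attr(f, "n_windows")
  out
}
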