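# Shared fixtures and independent oracles.  Everything is generated in code
# at test time; oracles are deliberately written as direct transcriptions
# (double loops, normal equations, oversampled correlation) independent of
# the package's computation paths.

# brute-force zero-normalized cross-correlation: direct double-loop
# evaluation over the window for every offset
ncc_oracle <- function(A, B, dys, dxs, anchor = c(1L, 1L)) {
  h <- nrow(A); w <- ncol(A)
  out <- matrix(NA_real_, length(dys), length(dxs))
  for (iy in seq_along(dys)) for (jx in seq_along(dxs)) {
    top <- anchor[1] + dys[iy]; left <- anchor[2] + dxs[jx]
    P <- B[top:(top + h - 1), left:(left + w - 1)]
    num <- 0; va <- 0; vb <- 0
    Am <- mean(A); Pm <- mean(P)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      da <- A[i, j] - Am; db <- P[i, j] - Pm
      num <- num + da * db; va <- va + da^2; vb <- vb + db^2
    }
    out[iy, jx] <- if (va == 0 || vb == 0) NaN else num / sqrt(va * vb)
  }
  out
}

# sinc (FFT zero-padding) upsampling of a real vector by integer factor U
fft_upsample <- function(x, U) {
  n <- length(x)
  X <- stats::fft(x)
  m <- n * U
  Y <- complex(m)
  half <- floor(n / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 0) Y[(m - half + 2):m] <- X[(n - half + 2):n]
  if (n %% 2 == 0) {  # split the Nyquist bin
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- X[half + 1] / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) * U / m
}

# oracle lag estimate: argmax of the finely oversampled cross-correlation
# of two real signals (positive lag = x2 delayed), searched on a sub-sample
# grid of pitch 1/U samples
xcorr_delay_oracle <- function(x1, x2, max_lag, U = 64) {
  x2u <- fft_upsample(x2, U)
  lags <- seq(-max_lag, max_lag, by = 1 / U)
  n <- length(x1)
  score <- vapply(lags, function(tau) {
    idx <- round(((seq_len(n) - 1) + tau) * U) + 1
    if (idx[1] < 1 || idx[n] > length(x2u)) return(-Inf)
    seg <- x2u[idx]
    sum(x1 * seg) / sqrt(sum(seg^2))     # normalized: amplitude-unbiased
  }, 0)
  lags[which.max(score)]
}

# sum-of-Gaussian-pulses test signal, evaluable at arbitrary (fractional)
# sample positions: a deterministic speckle-like RF line
pulse_train <- function(t, centers, amps, fs = 120e6, f0 = 7.5e6,
                        sigma = 10) {
  out <- numeric(length(t))
  for (k in seq_along(centers)) {
    tt <- t - centers[k]
    out <- out + amps[k] * exp(-tt^2 / (2 * sigma^2)) * cos(2 * pi * f0 / fs * tt)
  }
  out
}

# matched pre/post baseband lines with an exact constant fractional delay
delayed_line_pair <- function(n = 512, delay = 2, seed = 1,
                              fs = 120e6, f0 = 7.5e6) {
  set.seed(seed)
  centers <- sort(runif(round(n / 12), 20, n - 20))
  amps <- rnorm(length(centers))
  t <- seq_len(n) - 1
  x1 <- pulse_train(t, centers, amps, fs, f0)
  x2 <- pulse_train(t - delay, centers, amps, fs, f0)
  fr <- function(x) rf_frame(cbind(x, x), fs = fs, f0 = f0,
                             line_spacing = 2e-4)
  b1 <- demodulate(analytic_signal(fr(x1)))
  b2 <- demodulate(analytic_signal(fr(x2)))
  list(rf1 = x1, rf2 = x2, bb1 = b1[, 1], bb2 = b2[, 1],
       w0 = 2 * pi * f0 / fs)
}

# smooth speckle-like envelope field (for coarse block-matching tests)
speckle_env <- function(nr, nc, seed = 1, smooth = 3) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc)
  k <- stats::dnorm(seq(-2, 2, length.out = 2 * smooth + 1))
  m <- apply(m, 2, function(x) stats::filter(c(rep(0, smooth), x,
                                               rep(0, smooth)), k, sides = 2)[
                                                 (smooth + 1):(smooth + nr)])
  m <- t(apply(m, 1, function(x) stats::filter(c(rep(0, smooth), x,
                                                 rep(0, smooth)), k, sides = 2)[
                                                   (smooth + 1):(smooth + nc)]))
  abs(m) + 0.05
}

# shift a matrix down by dy rows and right by dx cols (zero fill)
shift_mat <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m) - abs(dy))
  src_c <- seq_len(ncol(m) - abs(dx))
  dst_r <- src_r + max(dy, 0); src_r <- src_r + max(-dy, 0)
  dst_c <- src_c + max(dx, 0); src_c <- src_c + max(-dx, 0)
  out[dst_r, dst_c] <- m[src_r, src_c]
  out
}

# reduced-size phantom configuration for fast end-to-end tests:
# 10 mm x 10 mm block, 2 mm inclusion, 64 lines, coarser mesh
test_cfg_small <- function(...) {
  default_config(width = 0.010, height = 0.010, incl_cz = 0.005,
                 incl_radius = 0.002, n_lines = 64, mesh_n = 32,
                 roi_radius = 1e-3, roi_bg_offset = 3.5e-3,
                 scatterer_density = 20, ...)
}

# build a strain_map object directly from a ground-truth strain grid (the
# "FEM-truth map"), with meta chosen so pixel coordinates equal the mesh
# centroid coordinates
truth_strain_map <- function(truth, fs = 120e6, c = 1540) {
  n <- length(truth$cy)
  dx <- truth$cx[2] - truth$cx[1]
  structure(list(strain = truth$strain,
                 centers_axial = truth$cy * 2 * fs / c,
                 centers_lateral = truth$cx / dx + (n + 1) / 2,
                 meta = list(fs = fs, c = c, line_spacing = dx,
                             n_lines = n)),
            class = "strain_map")
}

# is the TRUE region of a logical matrix a single connected component
# (4-connectivity) containing the given (row, col)?
single_blob_containing <- function(mask, row, col) {
  if (!mask[row, col]) return(FALSE)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  queue <- list(c(row, col)); lab[row, col] <- 1L
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
          q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
        lab[q[1], q[2]] <- 1L
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  all(lab[mask] == 1L)
}
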