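# Preprocessing: analytic signal, complex baseband, multirate pyramid.
#
# The envelope/phase split used downstream is envelope = Mod(baseband),
# phase = Arg(baseband); the coarse search consumes envelopes at the pyramid
# rates, the fine stage consumes the rate-1 baseband.

# analytic signal of one real vector via the FFT half-spectrum construction
analytic_vec <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Analytic signal of an RF frame
#'
#' Per scan line, returns the complex signal whose real part is the RF line
#' and whose imaginary part is its Hilbert transform.
#'
#' @param frame an [rf_frame()].
#' @return an `analytic_frame`: complex matrix `values` plus the source
#'   frame's metadata.
#' @export
analytic_signal <- function(frame) {
  validate_rf_frame(frame)
  t0 <- proc.time()[3]
  values <- apply(frame$samples, 2, analytic_vec)
  dim(values) <- dim(frame$samples)
  out <- structure(
    list(values = values, fs = frame$fs, f0 = frame$f0, c = frame$c,
         line_spacing = frame$line_spacing, depth_offset = frame$depth_offset),
    class = "analytic_frame")
  qse_log("preprocess", "analytic signal %dx%d in %.2fs",
          nrow(values), ncol(values), proc.time()[3] - t0)
  out
}

#' Demodulate an analytic frame to complex baseband
#'
#' Multiplies by `exp(-1i * w0 * t)` with `t = sample_index / fs` (0-based),
#' centering the spectrum near zero.  The modulus is unchanged.
#'
#' @param frame an `analytic_frame` from [analytic_signal()].
#' @param w0 demodulation angular frequency, rad/s; defaults to
#'   `2 * pi * f0`.  Values more than 25% away from the carrier trigger a
#'   warning; nonpositive values are an error.
#' @return complex baseband matrix with attribute `w0`.
#' @export
demodulate <- function(frame, w0 = 2 * pi * frame$f0) {
  if (!inherits(frame, "analytic_frame"))
    stop("demodulate: expected an analytic_frame", call. = FALSE)
  if (!is.numeric(w0) || length(w0) != 1L || w0 <= 0)
    stop("demodulate: w0 must be a positive scalar", call. = FALSE)
  w_ref <- 2 * pi * frame$f0
  if (abs(w0 - w_ref) > 0.25 * w_ref)
    warning(sprintf(
      "demodulate: w0 = %.3g rad/s is more than 25%% from the carrier %.3g",
      w0, w_ref), call. = FALSE)
  t <- (seq_len(nrow(frame$values)) - 1) / frame$fs
  bb <- frame$values * exp(-1i * w0 * t)
  attr(bb, "w0") <- w0
  attr(bb, "fs") <- frame$fs
  bb
}

# symmetric-FIR "same" convolution along columns (zero net group delay)
conv_same_cols <- function(m, h) {
  k <- (length(h) - 1) / 2
  n <- nrow(m)
  pad <- matrix(0, k, ncol(m))
  mp <- rbind(pad, m, pad)
  out <- stats::filter(mp, h, method = "convolution", sides = 2)
  out <- as.matrix(out)[(k + 1):(k + n), , drop = FALSE]
  out
}

# one-sided baseband bandwidth estimate: highest |f| at which the average
# line power spectrum is within 20 dB of its peak
baseband_bandwidth <- function(bb, fs) {
  n <- nrow(bb)
  P <- rowMeans(Mod(stats::mvfft(bb))^2)
  f <- (seq_len(n) - 1) / n * fs
  f[f >= fs / 2] <- f[f >= fs / 2] - fs  # wrap to [-fs/2, fs/2)
  keep <- P >= max(P) * 1e-2             # -20 dB
  max(abs(f[keep]))
}

#' Build a multirate baseband/envelope pyramid
#'
#' Each level holds the anti-alias-filtered, factor-`r` axially decimated
#' complex baseband and its envelope (modulus).  Decimation acts on the
#' axial (sample) axis only; scan lines are preserved.  Every requested rate
#' must respect the Nyquist condition `fs / r > 2 * B`, where `B` is the
#' 20 dB one-sided bandwidth of the baseband; the anti-alias filter is a
#' linear-phase lowpass FIR (cutoff `0.8 * (fs / r) / 2`) applied with zero
#' net delay.
#'
#' @param baseband complex matrix from [demodulate()].
#' @param rates integer downsample factors, strictly decreasing, last = 1.
#' @param w0 demodulation angular frequency, rad/s (defaults to the
#'   baseband's own attribute).
#' @param fs sampling frequency, Hz.
#' @param fir_taps anti-alias FIR order.
#' @return a `baseband_pyramid`: list of levels (`rate`, `baseband`,
#'   `envelope`) plus `w0` and `fs`.
#' @export
build_pyramid <- function(baseband, rates, w0 = attr(baseband, "w0"),
                          fs = attr(baseband, "fs"), fir_taps = 64) {
  if (is.null(w0) || is.null(fs))
    stop("build_pyramid: w0 and fs required", call. = FALSE)
  rates <- as.integer(rates)
  if (any(diff(rates) >= 0) || rates[length(rates)] != 1L)
    stop("build_pyramid: rates must be strictly decreasing and end at 1",
         call. = FALSE)
  B <- baseband_bandwidth(baseband, fs)
  t0 <- proc.time()[3]
  levels <- lapply(rates, function(r) {
    if (r > 1L && fs / r <= 2 * B)
      stop(sprintf(
        "build_pyramid: rate %d violates Nyquist (fs/r = %.3g MHz <= 2B, B = %.3g MHz)",
        r, fs / r / 1e6, B / 1e6), call. = FALSE)
    if (r == 1L) {
      bb <- baseband
    } else {
      h <- signal::fir1(fir_taps, 0.8 / r)
      bb <- conv_same_cols(Re(baseband), h) +
        1i * conv_same_cols(Im(baseband), h)
      bb <- bb[seq(1, nrow(bb), by = r), , drop = FALSE]
    }
    list(rate = r, baseband = bb, envelope = Mod(bb))
  })
  out <- structure(list(levels = levels, w0 = w0, fs = fs,
                        bandwidth = B),
                   class = "baseband_pyramid")
  qse_log("preprocess", "pyramid rates [%s], B = %.2f MHz, %.2fs",
          paste(rates, collapse = ","), B / 1e6, proc.time()[3] - t0)
  out
}

#' @exportS3Method base::print
print.baseband_pyramid <- function(x, ...) {
  cat(sprintf("<baseband_pyramid> %d levels, w0 = %.3g rad/s, B = %.2f MHz\n",
              length(x$levels), x$w0, x$bandwidth / 1e6))
  for (lv in x$levels)
    cat(sprintf("  rate %2d: %d x %d\n", lv$rate,
                nrow(lv$baseband), ncol(lv$baseband)))
  invisible(x)
}

# full preprocessing of one frame: analytic -> baseband -> pyramid
preprocess_frame <- function(frame, cfg) {
  an <- analytic_signal(frame)
  bb <- demodulate(an, 2 * pi * frame$f0)
  pyr <- build_pyramid(bb, c(cfg$rates, 1L), fir_taps = cfg$fir_taps)
  list(analytic = an, baseband = bb, pyramid = pyr)
}
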