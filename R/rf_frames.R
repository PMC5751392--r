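#' RF frame container
#'
#' Bundles a real-valued radio-frequency echo matrix (axial sample index in
#' rows, scan line index in columns) with the acquisition metadata every
#' downstream stage needs: sampling frequency, nominal transducer center
#' frequency, sound speed and lateral line spacing.  Axial sample `i`
#' (0-based) maps to depth `depth_offset + i * c / (2 * fs)` metres.
#'
#' @param samples numeric matrix, axial samples x scan lines (>= 64 x >= 2).
#' @param fs sampling frequency, Hz; must exceed `2 * f0`.
#' @param f0 nominal transducer center frequency, Hz.
#' @param c sound speed, m/s.
#' @param line_spacing lateral distance between adjacent scan lines, m.
#' @param depth_offset depth of the first sample, m.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, fs, f0, c = 1540, line_spacing,
                     depth_offset = 0) {
  frame <- structure(
    list(samples = samples, fs = fs, f0 = f0, c = c,
         line_spacing = line_spacing, depth_offset = depth_offset),
    class = "rf_frame")
  validate_rf_frame(frame)
  frame
}

validate_rf_frame <- function(frame) {
  s <- frame$samples
  if (!is.matrix(s) || !is.numeric(s))
    stop("rf_frame: samples must be a numeric matrix", call. = FALSE)
  if (ncol(s) < 2L)
    stop("rf_frame: at least 2 scan lines required", call. = FALSE)
  if (nrow(s) < 64L)
    stop("rf_frame: at least 64 axial samples required", call. = FALSE)
  for (key in c("fs", "f0", "c", "line_spacing", "depth_offset")) {
    v <- frame[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("rf_frame: metadata '%s' must be a finite scalar", key),
           call. = FALSE)
  }
  if (frame$fs <= 2 * frame$f0)
    stop("rf_frame: fs must exceed 2 * f0 (sampling above carrier Nyquist)",
         call. = FALSE)
  if (frame$c <= 0 || frame$line_spacing <= 0)
    stop("rf_frame: c and line_spacing must be positive", call. = FALSE)
  invisible(frame)
}

#' @exportS3Method base::print
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d axial samples x %d lines\n",
              nrow(x$samples), ncol(x$samples)))
  cat(sprintf("  fs = %.3f MHz, f0 = %.3f MHz, c = %.0f m/s\n",
              x$fs / 1e6, x$f0 / 1e6, x$c))
  cat(sprintf("  line spacing = %.4f mm, depth %.2f-%.2f mm\n",
              x$line_spacing * 1e3, x$depth_offset * 1e3,
              depth_axis(x)[nrow(x$samples)] * 1e3))
  invisible(x)
}

#' Depth coordinate of every axial sample
#'
#' @param frame an [rf_frame()].
#' @return numeric vector of depths in metres, strictly increasing.
#' @export
depth_axis <- function(frame) {
  frame$depth_offset + (seq_len(nrow(frame$samples)) - 1) *
    frame$c / (2 * frame$fs)
}

#' Lateral coordinate of every scan line
#'
#' Lines are centered on the aperture: line `l` (1-based) sits at
#' `(l - (n + 1) / 2) * line_spacing` metres.
#'
#' @param frame an [rf_frame()] (or anything with `line_spacing` and a
#'   `samples` matrix).
#' @return numeric vector of lateral positions in metres.
#' @export
lateral_axis <- function(frame) {
  n <- ncol(frame$samples)
  (seq_len(n) - (n + 1) / 2) * frame$line_spacing
}

FRAME_META_KEYS <- c("fs", "f0", "c", "line_spacing", "depth_offset")

#' Write an RF frame to disk
#'
#' On-disk container: a flat little-endian float32 binary payload in
#' column-major (axial-fastest) order at `path`, plus a self-describing JSON
#' sidecar `<path>.json` holding `nrow`, `ncol` and the scalar metadata keys
#' `fs`, `f0`, `c`, `line_spacing`, `depth_offset`.  Writes are atomic
#' (temporary file then rename).
#'
#' @param frame an [rf_frame()].
#' @param path payload file path; the sidecar is written next to it.
#' @export
write_frame <- function(frame, path) {
  validate_rf_frame(frame)
  meta <- c(list(nrow = nrow(frame$samples), ncol = ncol(frame$samples),
                 dtype = "float32"),
            frame[FRAME_META_KEYS])
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "wb")
  ok <- FALSE
  tryCatch({
    writeBin(as.vector(frame$samples), con, size = 4L, endian = "little")
    ok <- TRUE
  }, finally = close(con))
  if (!ok) stop("write_frame: I/O error writing payload", call. = FALSE)
  tmpj <- paste0(path, ".json.tmp")
  jsonlite::write_json(meta, tmpj, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  file.rename(tmpj, paste0(path, ".json"))
  invisible(path)
}

#' Read an RF frame written by [write_frame()]
#'
#' @param path payload file path (the `<path>.json` sidecar must exist).
#' @return an [rf_frame()]; metadata round-trips exactly, payload at float32
#'   precision.
#' @export
read_frame <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_frame: no such file '%s'", path), call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("read_frame: missing metadata sidecar '%s'", sidecar),
         call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("nrow", "ncol", FRAME_META_KEYS))
    if (is.null(meta[[key]]))
      stop(sprintf("read_frame: metadata key '%s' missing", key),
           call. = FALSE)
  n <- as.integer(meta$nrow) * as.integer(meta$ncol)
  expected_bytes <- 4 * n
  if (file.size(path) != expected_bytes)
    stop(sprintf(
      "read_frame: payload is %d bytes but metadata implies %d (%d x %d float32)",
      file.size(path), expected_bytes, meta$nrow, meta$ncol), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  rf_frame(matrix(x, nrow = meta$nrow, ncol = meta$ncol),
           fs = as.numeric(meta$fs), f0 = as.numeric(meta$f0),
           c = as.numeric(meta$c),
           line_spacing = as.numeric(meta$line_spacing),
           depth_offset = as.numeric(meta$depth_offset))
}

# internal: same binary+sidecar layout for bare numeric matrices (ground
# truth grids etc.); stored as float64 to keep truth fields exact.
write_matrix_bin <- function(m, path) {
  meta <- list(nrow = nrow(m), ncol = ncol(m), dtype = "float64")
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "wb")
  tryCatch(writeBin(as.vector(m), con, size = 8L, endian = "little"),
           finally = close(con))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

read_matrix_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$nrow * meta$ncol, size = 8L,
               endian = "little")
  matrix(x, nrow = meta$nrow, ncol = meta$ncol)
}

# lightweight stage logging, enabled with options(qselast.verbose = TRUE)
qse_log <- function(stage, ...) {
  if (isTRUE(getOption("qselast.verbose", FALSE)))
    message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}
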