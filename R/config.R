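# Run configuration: every tunable of every stage, with units and admissible
# ranges.  The table drives both default construction and the validation of
# text config files (one "key = value" per line, '#' comments).

config_table <- function() {
  # type: num | int | numvec | intvec | str
  e <- function(name, default, min = -Inf, max = Inf, type = "num",
                units = "", doc = "") {
    list(name = name, default = default, min = min, max = max, type = type,
         units = units, doc = doc)
  }
  entries <- list(
    # acquisition / transducer
    e("fs", 120e6, 1e6, 1e10, "num", "Hz", "RF sampling frequency"),
    e("f0", 7.5e6, 1e5, 1e9, "num", "Hz", "transducer center frequency"),
    e("c", 1540, 100, 1e4, "num", "m/s", "sound speed"),
    e("n_lines", 128, 2, 4096, "int", "lines", "scan lines per frame"),
    e("line_spacing", NA_real_, 1e-6, 1e-2, "num", "m",
      "lateral line pitch; NA = phantom width / n_lines"),
    e("pulse_bw", 0.6, 0.05, 1.5, "num", "fraction",
      "-6 dB fractional pulse bandwidth"),
    e("beam_sigma", 4e-4, 1e-5, 5e-3, "num", "m",
      "lateral Gaussian beam sigma"),
    e("scatterer_density", 20, 0.5, 1000, "num", "mm^-2",
      "expected scatterers per square millimetre"),
    e("noise_snr", 30, -10, 200, "num", "dB", "additive white noise SNR"),
    # phantom geometry / material
    e("width", 0.020, 1e-3, 1, "num", "m", "phantom width"),
    e("height", 0.020, 1e-3, 1, "num", "m", "phantom height (depth extent)"),
    e("incl_radius", 0.003, 0, 0.5, "num", "m", "inclusion radius"),
    e("incl_cx", 0, -0.5, 0.5, "num", "m", "inclusion lateral center"),
    e("incl_cz", 0.010, 0, 1, "num", "m", "inclusion depth center"),
    e("E_inclusion", 1e5, 1, 1e9, "num", "Pa", "inclusion Young's modulus"),
    e("E_background", 1.293e4, 1, 1e9, "num", "Pa",
      "background Young's modulus (see calibrate_contrast)"),
    e("poisson", 0.495, 0, 0.499999, "num", "", "Poisson's ratio (< 0.5)"),
    e("density", 1000, 1, 1e5, "num", "kg/m^3", "material density"),
    e("compression", 6e-4, 0, 0.1, "num", "m",
      "applied top-surface axial compression"),
    e("mesh_n", 80, 8, 512, "int", "elements", "FEM elements per side"),
    e("bottom_bc", "slip", type = "str", units = "",
      doc = "bottom boundary: slip (axially fixed) or clamped"),
    # preprocessing
    e("rates", c(8, 4, 2), 1, 64, "intvec", "",
      "pyramid downsample rates, coarse to fine (last feeds level 3)"),
    e("fir_taps", 64, 8, 512, "int", "taps", "anti-alias FIR order"),
    # coarse estimation
    e("l1_win_wavelengths", 10, 1, 100, "num", "wavelengths",
      "level-1 calculation-window axial extent"),
    e("l1_win_lines", 10, 4, 64, "int", "lines",
      "level-1 calculation-window lateral extent"),
    e("expected_max_strain", 0.05, 1e-4, 0.2, "num", "",
      "strain level the search ranges are sized for"),
    e("corr_floor", 0.3, -1, 1, "num", "", "validity floor on peak NCC"),
    e("stencil_half", 2, 1, 5, "int", "", "tracking stencil half-width (2 = 5x5)"),
    e("track_max_steps", 50, 1, 1000, "int", "", "tracking step cap"),
    e("l2_bound_h", 10, 1, 200, "int", "samples",
      "level-2 axial search half-range about the initial point"),
    e("l2_bound_w", 3, 1, 64, "int", "lines", "level-2 lateral half-range"),
    e("l3_bound_h", 6, 1, 200, "int", "samples", "level-3 axial half-range"),
    e("l3_bound_w", 2, 1, 64, "int", "lines", "level-3 lateral half-range"),
    e("l3_overlap", 0.5, 0, 0.95, "num", "fraction", "level-3 window overlap"),
    e("sg_window", 9, 3, 201, "int", "grid points",
      "Savitzky-Golay window for lateral smoothing (odd)"),
    e("sg_order", 2, 0, 10, "int", "", "Savitzky-Golay polynomial order"),
    e("lateral_sig_threshold", 0.25, 0, 100, "num", "lines",
      "smoothed lateral shifts below this are zeroed"),
    # fine estimation
    e("fine_T", 25, 5, 1000, "int", "samples", "fine window length"),
    e("fine_overlap", 0.75, 0, 0.99, "num", "fraction", "fine window overlap"),
    e("newton_tol", 1e-3, 1e-9, 1, "num", "samples",
      "phase zero-crossing convergence tolerance"),
    e("newton_max_iter", 20, 1, 1000, "int", "", "Newton iteration cap"),
    e("ds_rate", 2, 1, 16, "int", "", "downsampled-1D baseline rate"),
    # strain + metrics
    e("lsqse_kernel", 41, 3, 999, "int", "grid points",
      "least-squares strain fit kernel (odd)"),
    e("roi_radius", 1.5e-3, 1e-5, 0.1, "num", "m", "metric ROI radius"),
    e("roi_bg_offset", 6.5e-3, 0, 0.5, "num", "m",
      "lateral offset of the background ROI from the inclusion center"),
    # study orchestration
    e("strain_levels", c(0.002, 0.004, 0.006, 0.008, 0.010, 0.015,
                         0.020, 0.025, 0.030, 0.035, 0.040),
      0, 0.1, "numvec", "", "applied strain sweep"),
    e("n_seeds", 5, 1, 1000, "int", "", "speckle realizations per level"),
    e("seed", 1, 1, 2^31 - 1, "int", "", "base random seed"),
    e("cnre_distinguish", 2, 0, 1e6, "num", "",
      "CNRe below this counts as lesion/background indistinguishable")
  )
  names(entries) <- vapply(entries, `[[`, "", "name")
  entries
}

#' Default run configuration
#'
#' Returns the full configuration preset used throughout: a 7.5 MHz linear
#' array sampled at 120 MHz with 128 scan lines over a 20 mm x 20 mm
#' phantom carrying a 3 mm-radius stiff inclusion (strain contrast 5,
#' Poisson 0.495), and the estimator tunables documented in
#' [config_describe()].
#'
#' @param ... named overrides of individual keys.
#' @return an object of class `qse_config` (named list).
#' @export
default_config <- function(...) {
  tab <- config_table()
  cfg <- lapply(tab, `[[`, "default")
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop(sprintf("unknown config key(s): %s\nvalid keys: %s",
                   paste(bad, collapse = ", "),
                   paste(names(cfg), collapse = ", ")), call. = FALSE)
    cfg[names(over)] <- over
  }
  cfg <- structure(cfg, class = "qse_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  tab <- config_table()
  for (key in names(tab)) {
    spec <- tab[[key]]
    v <- cfg[[key]]
    if (spec$type == "str") {
      if (key == "bottom_bc" && !v %in% c("slip", "clamped"))
        stop("config: bottom_bc must be 'slip' or 'clamped'", call. = FALSE)
      next
    }
    if (length(v) == 1L && is.na(v)) next  # NA = derived default
    if (!is.numeric(v) || any(!is.finite(v)))
      stop(sprintf("config: '%s' must be numeric and finite", key),
           call. = FALSE)
    if (any(v < spec$min) || any(v > spec$max))
      stop(sprintf("config: '%s' out of range [%g, %g] (%s)",
                   key, spec$min, spec$max, spec$units), call. = FALSE)
    if (spec$type %in% c("int", "intvec") && any(v != round(v)))
      stop(sprintf("config: '%s' must be integer-valued", key), call. = FALSE)
  }
  if (cfg$sg_window %% 2 == 0)
    stop("config: sg_window must be odd", call. = FALSE)
  if (cfg$sg_window <= cfg$sg_order)
    stop("config: sg_window must exceed sg_order", call. = FALSE)
  if (cfg$lsqse_kernel %% 2 == 0)
    stop("config: lsqse_kernel must be odd", call. = FALSE)
  r <- cfg$rates
  if (any(diff(r) >= 0) || r[length(r)] < 1)
    stop("config: rates must be strictly decreasing", call. = FALSE)
  if (cfg$fs <= 2 * cfg$f0)
    stop("config: fs must exceed 2 * f0", call. = FALSE)
  invisible(cfg)
}

#' Describe every configuration key
#'
#' @return data.frame of key, default, range, units and description.
#' @export
config_describe <- function() {
  tab <- config_table()
  data.frame(
    key = names(tab),
    default = vapply(tab, function(s) paste(format(s$default), collapse = ","),
                     ""),
    min = vapply(tab, function(s) if (s$type == "str") NA_real_ else s$min, 0),
    max = vapply(tab, function(s) if (s$type == "str") NA_real_ else s$max, 0),
    units = vapply(tab, `[[`, "", "units"),
    doc = vapply(tab, `[[`, "", "doc"),
    row.names = NULL)
}

#' Load a run configuration from a text file
#'
#' The file holds one `key = value` assignment per line; blank lines and
#' `#` comments are ignored.  Vector-valued keys take comma-separated
#' values.  Keys not present take the documented defaults; unknown keys and
#' out-of-range values are errors.
#'
#' @param path config file path.
#' @return a validated `qse_config`; the effective configuration is logged.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("load_config: no such file '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  tab <- config_table()
  cfg <- lapply(tab, `[[`, "default")
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("load_config: cannot parse line '%s'", ln), call. = FALSE)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% names(tab))
      stop(sprintf("load_config: unknown key '%s'\nvalid keys: %s",
                   key, paste(names(tab), collapse = ", ")), call. = FALSE)
    spec <- tab[[key]]
    cfg[[key]] <- switch(spec$type,
      str = val,
      numvec = ,
      intvec = as.numeric(strsplit(val, ",")[[1]]),
      as.numeric(val))
    if (spec$type != "str" && any(is.na(cfg[[key]])))
      stop(sprintf("load_config: non-numeric value for '%s'", key),
           call. = FALSE)
  }
  cfg <- structure(cfg, class = "qse_config")
  validate_config(cfg)
  qse_log("config", "loaded %s (%d keys set, hash %s)", path, length(lines),
          config_hash(cfg))
  cfg
}

# order-independent short hash of the effective configuration, for logs
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17), collapse = ","), ""),
    sep = "=", collapse = ";")
  u <- utf8ToInt(s)
  h <- sum(u * (seq_along(u) %% 97 + 1)) %% 0xFFFFFFF
  sprintf("%07x", h)
}

#' @exportS3Method base::print
print.qse_config <- function(x, ...) {
  cat(sprintf("<qse_config> %d keys, hash %s\n", length(x), config_hash(x)))
  cat(sprintf("  fs = %g MHz, f0 = %g MHz, %d lines, rates = [%s]\n",
              x$fs / 1e6, x$f0 / 1e6, x$n_lines,
              paste(x$rates, collapse = ", ")))
  invisible(x)
}

# effective line spacing (NA in the config means width / n_lines)
cfg_line_spacing <- function(cfg) {
  if (is.na(cfg$line_spacing)) cfg$width / cfg$n_lines else cfg$line_spacing
}
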