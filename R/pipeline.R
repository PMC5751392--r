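# Top-level estimator: one call takes a pre/post RF frame pair through
# preprocessing, (for the 2D hybrid) the three-level coarse search, the
# phase zero-crossing fine stage, LSQSE strain reconstruction and the
# quality metrics, returning a classed object with print/summary/plot
# methods.

#' Estimate a strain image from a pre/post-compression RF pair
#'
#' Runs one of three displacement-estimation pipelines and reconstructs the
#' axial strain map:
#'
#' * `"hybrid2d"` — the 2D multiresolution hybrid method: three-level NCC
#'   block matching on the envelope pyramid, Savitzky-Golay-smoothed
#'   lateral compensation, then per-window coarse-initialized phase
#'   zero-crossing refinement.
#' * `"pz1d"` — the original 1D phase zero-crossing estimator (windows
#'   chained along each line, no lateral compensation).
#' * `"pz1d_ds"` — the chained 1D estimator on axially decimated baseband.
#'
#' @param pre,post [rf_frame()] objects with identical geometry.
#' @param method estimation pipeline (see above).
#' @param config a [default_config()] (or [load_config()] result).
#' @param metrics compute ROI metrics (CNRe, strain ratio, area ratio)?
#'   Requires the default ROIs to fit inside the map; disable for
#'   non-phantom geometries.
#' @param rois optional list with `inclusion` and `background`
#'   [roi_spec()]s; defaults to the configured phantom ROIs.
#' @return an object of class `strain_image`: the displacement `field`, the
#'   strain `map`, the `binary` image, `metrics`, and the coarse grids
#'   (hybrid method only).
#' @export
strain_image <- function(pre, post,
                         method = c("hybrid2d", "pz1d", "pz1d_ds"),
                         config = default_config(), metrics = TRUE,
                         rois = NULL) {
  method <- match.arg(method)
  validate_rf_frame(pre); validate_rf_frame(post)
  if (!identical(dim(pre$samples), dim(post$samples)))
    stop("strain_image: pre/post frame shapes differ", call. = FALSE)
  cfg <- config
  t_start <- proc.time()[3]
  pz <- phase_zero_config(window_T = cfg$fine_T, overlap = cfg$fine_overlap,
                          w0 = 2 * pi * pre$f0 / pre$fs,
                          max_iter = cfg$newton_max_iter,
                          tol = cfg$newton_tol,
                          init_mode = if (method == "hybrid2d") "coarse"
                                      else "chained")
  coarse <- NULL
  if (method == "hybrid2d") {
    pp <- preprocess_frame(pre, cfg)
    qq <- preprocess_frame(post, cfg)
    coarse <- coarse_pipeline(pp$pyramid, qq$pyramid, cfg)
    ctr <- fine_centers(nrow(pre$samples), pz$window_T, pz$overlap)
    lines <- seq_len(ncol(pre$samples))
    g3 <- coarse$level3
    g3$lateral <- g3$lateral_final
    init <- interp_grid(g3, ctr, lines,
                        scale_axial = coarse$rate3, scale_lateral = 1)
    field <- fine_field_modified(pp$pyramid$levels[[4]]$baseband,
                                 qq$pyramid$levels[[4]]$baseband,
                                 init$axial, init$lateral, pz)
  } else if (method == "pz1d") {
    bb1 <- demodulate(analytic_signal(pre))
    bb2 <- demodulate(analytic_signal(post))
    field <- fine_field_chained_1d(bb1, bb2, pz)
  } else {
    field <- fine_field_downsampled_1d(pre, post, cfg$ds_rate, pz,
                                       fir_taps = cfg$fir_taps)
  }
  meta <- list(fs = pre$fs, c = pre$c, line_spacing = pre$line_spacing,
               n_lines = ncol(pre$samples))
  map <- strain_map(field, cfg$lsqse_kernel, meta)
  binary <- binarize(map)
  met <- NULL
  if (metrics) {
    if (is.null(rois)) rois <- default_rois(cfg)
    met <- list(cnre = cnre(map, rois$inclusion, rois$background),
                strain_ratio = strain_ratio(map, rois$inclusion,
                                            rois$background),
                area_ratio = inclusion_area_ratio(binary))
  }
  structure(list(method = method, config = cfg, field = field, map = map,
                 binary = binary, metrics = met, rois = rois,
                 elapsed = proc.time()[3] - t_start,
                 coarse = coarse, call = match.call()),
            class = "strain_image")
}

#' @exportS3Method base::print
print.strain_image <- function(x, ...) {
  cat(sprintf("<strain_image> method = %s, %d x %d strain pixels\n",
              x$method, nrow(x$map$strain), ncol(x$map$strain)))
  cat(sprintf("  mean strain %.3f%%, %.1f%% windows converged\n",
              100 * mean(x$map$strain), 100 * mean(x$field$converged)))
  if (!is.null(x$metrics))
    cat(sprintf("  CNRe = %.2f, strain ratio = %.2f, area ratio = %.4f\n",
                x$metrics$cnre, x$metrics$strain_ratio,
                x$metrics$area_ratio))
  invisible(x)
}

#' @exportS3Method base::summary
summary.strain_image <- function(object, ...) {
  s <- object$map$strain
  out <- list(
    method = object$method,
    strain_quantiles = stats::quantile(s, c(0.05, 0.25, 0.5, 0.75, 0.95)),
    mean_strain = mean(s),
    converged_fraction = mean(object$field$converged),
    mean_iterations = mean(object$field$iterations),
    metrics = object$metrics,
    elapsed = object$elapsed)
  class(out) <- "summary.strain_image"
  out
}

#' @exportS3Method base::print
print.summary.strain_image <- function(x, ...) {
  cat(sprintf("Strain image (%s pipeline)\n", x$method))
  cat(sprintf("  mean strain: %.4f%%\n", 100 * x$mean_strain))
  cat("  strain quantiles (%):\n")
  print(round(100 * x$strain_quantiles, 4))
  cat(sprintf("  converged windows: %.1f%% (mean %.1f Newton iterations)\n",
              100 * x$converged_fraction, x$mean_iterations))
  if (!is.null(x$metrics))
    cat(sprintf("  CNRe = %.3f  strain ratio = %.3f  area ratio = %.4f\n",
                x$metrics$cnre, x$metrics$strain_ratio,
                x$metrics$area_ratio))
  cat(sprintf("  elapsed: %.2f s\n", x$elapsed))
  invisible(x)
}

#' Plot a strain image
#'
#' @param x a `strain_image`.
#' @param what `"strain"` or `"binary"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.strain_image <- function(x, what = c("strain", "binary"), ...) {
  what <- match.arg(what)
  co <- map_coords(x$map)
  z <- if (what == "strain") x$map$strain else x$binary * 1
  graphics::image(x = co$depth * 1e3, y = co$lateral * 1e3,
                  z = z, xlab = "depth (mm)", ylab = "lateral (mm)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = sprintf("%s (%s)", what, x$method), ...)
  invisible(x)
}
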