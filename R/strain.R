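# Strain reconstruction (least-squares strain estimator) and image-quality
# metrics: elastographic contrast-to-noise ratio, strain ratio, mean-
# thresholded binary strain image and inclusion area ratio.

#' Least-squares strain along one displacement profile
#'
#' At each interior position the strain is the slope of the least-squares
#' line fit of displacement `u` against depth `z` over a centered kernel of
#' odd length (piecewise linear fitting).  With both `u` and `z` in sample
#' units the result is dimensionless.
#'
#' @param u axial displacement vector, samples.
#' @param z depth coordinates, samples; must be uniformly spaced.
#' @param kernel odd fit-window length, `3 <= kernel <= length(u)`.
#' @return strain vector of length `length(u) - kernel + 1` (the raw
#'   displacement gradient; no sign flip here).
#' @export
lsqse_line <- function(u, z, kernel) {
  kernel <- as.integer(kernel)
  if (kernel %% 2 == 0 || kernel < 3)
    stop("lsqse_line: kernel must be odd and >= 3", call. = FALSE)
  if (kernel > length(u))
    stop("lsqse_line: kernel exceeds profile length", call. = FALSE)
  dz <- diff(z)
  if (any(abs(dz - dz[1]) > 1e-9 * abs(dz[1])))
    stop("lsqse_line: depth coordinates must be uniformly spaced",
         call. = FALSE)
  m <- (kernel - 1L) / 2L
  i <- seq(-m, m)
  w <- i / (sum(i^2) * dz[1])          # closed-form LS slope weights
  # stats::filter convolution reverses the kernel; slope weights are odd
  out <- stats::filter(u, rev(w), method = "convolution", sides = 2)
  as.numeric(out[(m + 1):(length(u) - m)])
}

#' Axial strain map from a displacement field
#'
#' Applies [lsqse_line()] down every scan-line column of the axial
#' displacement field.  Sign convention: the applied compression is
#' reported as positive strain (the displacement gradient is negated once,
#' here).
#'
#' @param field a [displacement_field()].
#' @param kernel odd LSQSE kernel length (fine-grid points).
#' @param meta list with `fs`, `c`, `line_spacing`, `n_lines` used to map
#'   grid coordinates to metres for ROI work (taken from the source frame).
#' @return a `strain_map`: `strain` matrix, trimmed `centers_axial`
#'   (finest-rate samples), `centers_lateral` (lines) and `meta`.
#' @export
strain_map <- function(field, kernel, meta) {
  m <- (as.integer(kernel) - 1L) / 2L
  s <- apply(field$axial, 2, lsqse_line, z = field$centers_axial,
             kernel = kernel)
  s <- matrix(s, ncol = ncol(field$axial))
  ctr <- field$centers_axial[(m + 1):(length(field$centers_axial) - m)]
  structure(list(strain = -s, centers_axial = ctr,
                 centers_lateral = field$centers_lateral, meta = meta),
            class = "strain_map")
}

#' @exportS3Method base::print
print.strain_map <- function(x, ...) {
  cat(sprintf("<strain_map> %d x %d, mean %.4f%%, range [%.4f, %.4f]%%\n",
              nrow(x$strain), ncol(x$strain), 100 * mean(x$strain),
              100 * min(x$strain), 100 * max(x$strain)))
  invisible(x)
}

#' Region of interest for strain statistics
#'
#' @param shape `"circle"` or `"rectangle"`.
#' @param center `(depth, lateral)` in metres.
#' @param radius circle radius, m (for `shape = "circle"`).
#' @param half_extents `(depth, lateral)` half-extents, m (rectangle).
#' @param role `"inclusion"` or `"background"`.
#' @return an `roi_spec`.
#' @export
roi_spec <- function(shape = c("circle", "rectangle"), center, radius = NULL,
                     half_extents = NULL, role = c("inclusion", "background")) {
  shape <- match.arg(shape); role <- match.arg(role)
  if (shape == "circle" && (is.null(radius) || radius <= 0))
    stop("roi_spec: circle needs a positive radius", call. = FALSE)
  if (shape == "rectangle" && (is.null(half_extents) ||
                               any(half_extents <= 0)))
    stop("roi_spec: rectangle needs positive half_extents", call. = FALSE)
  structure(list(shape = shape, center = center, radius = radius,
                 half_extents = half_extents, role = role),
            class = "roi_spec")
}

# physical coordinates of strain-map pixels
map_coords <- function(map) {
  meta <- map$meta
  depth <- map$centers_axial * meta$c / (2 * meta$fs)
  lateral <- (map$centers_lateral - (meta$n_lines + 1) / 2) *
    meta$line_spacing
  list(depth = depth, lateral = lateral)
}

# logical pixel mask of an ROI on a strain map
roi_mask <- function(map, roi) {
  co <- map_coords(map)
  D <- matrix(co$depth, length(co$depth), length(co$lateral))
  L <- matrix(co$lateral, length(co$depth), length(co$lateral), byrow = TRUE)
  if (roi$shape == "circle") {
    (D - roi$center[1])^2 + (L - roi$center[2])^2 <= roi$radius^2
  } else {
    abs(D - roi$center[1]) <= roi$half_extents[1] &
      abs(L - roi$center[2]) <= roi$half_extents[2]
  }
}

# default inclusion/background ROIs for a given config
default_rois <- function(cfg) {
  list(
    inclusion = roi_spec("circle", c(cfg$incl_cz, cfg$incl_cx),
                         radius = cfg$roi_radius, role = "inclusion"),
    background = roi_spec("circle",
                          c(cfg$incl_cz, cfg$incl_cx + cfg$roi_bg_offset),
                          radius = cfg$roi_radius, role = "background"))
}

roi_pixels <- function(map, roi, min_pixels = 25) {
  px <- map$strain[roi_mask(map, roi)]
  if (length(px) < min_pixels)
    stop(sprintf("ROI (%s) contains only %d strain pixels (>= %d required)",
                 roi$role, length(px), min_pixels), call. = FALSE)
  px
}

#' Elastographic contrast-to-noise ratio
#'
#' `CNRe = 2 (s1 - s2)^2 / (var1 + var2)` with means and variances of the
#' strain pixels inside the inclusion and background ROIs.  Larger is
#' better; the value is invariant under any affine rescaling of the strain
#' map.
#'
#' @param map a [strain_map()].
#' @param roi_inc,roi_bg [roi_spec()] regions (>= 25 pixels each).
#' @return dimensionless CNRe; `Inf` (with a warning) when both ROI
#'   variances are zero.
#' @export
cnre <- function(map, roi_inc, roi_bg) {
  s1 <- roi_pixels(map, roi_inc)
  s2 <- roi_pixels(map, roi_bg)
  v <- stats::var(s1) + stats::var(s2)
  if (v == 0) {
    warning("cnre: zero total ROI variance, returning Inf", call. = FALSE)
    return(Inf)
  }
  2 * (mean(s1) - mean(s2))^2 / v
}

#' Background-to-inclusion strain ratio
#'
#' Mean background strain divided by mean inclusion strain, so that a
#' phantom whose strain contrast is set to 5 reads as approximately 5.
#'
#' @inheritParams cnre
#' @return dimensionless ratio; `Inf` with a warning when the inclusion
#'   mean is (near) zero.
#' @export
strain_ratio <- function(map, roi_inc, roi_bg) {
  s1 <- mean(roi_pixels(map, roi_inc))
  s2 <- mean(roi_pixels(map, roi_bg))
  if (abs(s1) < .Machine$double.eps * 100) {
    warning("strain_ratio: near-zero inclusion mean, returning Inf",
            call. = FALSE)
    return(Inf)
  }
  s2 / s1
}

#' Mean-thresholded binary strain image
#'
#' A pixel is black (`TRUE`) where its strain is strictly below the
#' whole-map mean; the low-strain stiff inclusion therefore appears black.
#'
#' @param map a [strain_map()].
#' @return logical matrix, same shape as the strain map.
#' @export
binarize <- function(map) {
  if (any(!is.finite(map$strain)))
    stop("binarize: strain map must be finite", call. = FALSE)
  map$strain < mean(map$strain)
}

#' Inclusion area ratio
#'
#' Fraction of black pixels in a binary strain image; compared against the
#' geometric inclusion fraction `pi r^2 / (width * height)`.
#'
#' @param binary logical matrix from [binarize()].
#' @return fraction in `[0, 1]`.
#' @export
inclusion_area_ratio <- function(binary) {
  if (length(binary) == 0)
    stop("inclusion_area_ratio: empty image", call. = FALSE)
  mean(binary)
}
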