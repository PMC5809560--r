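#' GLCM configuration
#'
#' Bundles every tunable of the texture-extraction stage so that a single
#' object can be threaded through patch extraction, feature construction and
#' the bag-of-features pipeline.
#'
#' @param levels Number of gray-level quantization bins used for the
#'   co-occurrence matrix. 8-bit input is binned linearly from \[0, 255\] into
#'   `levels` bins before counting. An 8x8 region of interest holds only 64
#'   pixels, so the default of 8 levels keeps the matrix well populated.
#' @param d Pixel pair offset distance (default 1, nearest neighbor).
#' @param symmetric Count each pixel pair in both directions so the matrix is
#'   symmetric (Haralick convention). Default `TRUE`.
#' @param nbins Number of histogram bins used when summarizing the per-ROI
#'   parameter values of a patch into its feature vector. Default 22.
#' @param signal_threshold Gray level above which a pixel counts as signal
#'   (default 10 on the 8-bit scale).
#' @param min_signal_fraction Minimum fraction of signal pixels for a patch to
#'   be kept (default 0.25; the comparison is inclusive at patch level).
#'
#' @return A list of class `glcm_config`.
#' @export
#' @examples
#' cfg <- glcm_config()
#' cfg$levels
glcm_config <- function(levels = 8L, d = 1L, symmetric = TRUE, nbins = 22L,
                        signal_threshold = 10, min_signal_fraction = 0.25) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop_shg("shgbof_invalid_parameter", "levels must be an integer >= 2")
  if (d < 1) stop_shg("shgbof_invalid_parameter", "d must be >= 1")
  if (nbins < 1) stop_shg("shgbof_invalid_parameter", "nbins must be >= 1")
  structure(list(levels = levels, d = as.integer(d),
                 symmetric = isTRUE(symmetric), nbins = as.integer(nbins),
                 signal_threshold = signal_threshold,
                 min_signal_fraction = min_signal_fraction),
            class = "glcm_config")
}

#' Quantize 8-bit gray levels
#'
#' Linear binning of \[0, 255\] into `levels` equal right-open bins (the top
#' bin is closed so 255 maps to `levels - 1`). Order-preserving.
#'
#' @param x Integer matrix (or vector) of gray levels in \[0, 255\].
#' @param levels Number of output levels, >= 2. `levels = 256` is the
#'   identity on 8-bit input.
#' @return Object of the same shape with values in \[0, levels - 1\].
#' @export
#' @examples
#' quantize_levels(c(0, 128, 255), levels = 2)
quantize_levels <- function(x, levels) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop_shg("shgbof_invalid_parameter", "levels must be an integer >= 2")
  if (any(x < 0 | x > 255))
    stop_shg("shgbof_range_error", "gray levels must lie in [0, 255]")
  q <- pmin(as.integer(floor(as.numeric(x) * levels / 256)), levels - 1L)
  if (is.matrix(x)) q <- matrix(q, nrow = nrow(x))
  q
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs separated by distance `d` along orientation
#' `theta` and normalizes by the total count. Gray levels must already be
#' quantized to \[0, levels - 1\] (see [quantize_levels()]).
#'
#' Offset convention, (row, col) 0-based with top-left origin:
#' theta 0 pairs (r, c) with (r, c + d); 90 with (r - d, c); 45 with
#' (r - d, c + d); 135 with (r - d, c - d). With `symmetric = TRUE` every
#' pair is also counted in the reverse direction, so p equals its transpose.
#'
#' @param roi Integer matrix of quantized gray levels.
#' @param theta Orientation in degrees: 0, 45, 90 or 135.
#' @param d Offset distance (default 1).
#' @param levels Number of gray levels (matrix dimension).
#' @param symmetric Symmetric counting flag (default TRUE).
#' @return Object of class `glcm`: list with `p` (levels x levels probability
#'   matrix summing to 1), `levels`, `d`, `theta`, `symmetric`.
#' @export
#' @examples
#' roi <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
#' g <- glcm(roi, theta = 0, levels = 2)
#' sum(g$p)
glcm <- function(roi, theta, d = 1L, levels = max(roi) + 1L,
                 symmetric = TRUE) {
  if (!is.matrix(roi)) stop_shg("shgbof_shape_error", "roi must be a matrix")
  if (!theta %in% THETAS)
    stop_shg("shgbof_invalid_parameter", "theta must be one of 0, 45, 90, 135")
  storage.mode(roi) <- "integer"
  p <- tryCatch(
    cpp_glcm(roi, as.integer(d), as.integer(theta), as.integer(levels),
             isTRUE(symmetric)),
    error = function(e) stop_shg("shgbof_empty_pairs", conditionMessage(e)))
  structure(list(p = p, levels = as.integer(levels), d = as.integer(d),
                 theta = as.integer(theta), symmetric = isTRUE(symmetric)),
            class = "glcm")
}

#' Haralick texture parameters of a GLCM
#'
#' Computes the eight second-order texture statistics used throughout the
#' package: correlation, angular second moment (ASM), contrast, inverse
#' difference moment (IDM), entropy, sum entropy, sum average and sum
#' variance. Gray-level indices are 0-based, so the diagonal sum index runs
#' over \[0, 2(N-1)\].
#'
#' Conventions: entropies are returned as `-sum(p * log(p))` with natural
#' logarithm and `0 * log(0) == 0`; correlation uses the marginal means and
#' standard deviations of the row/column distributions and is 0 by convention
#' when either marginal standard deviation vanishes (constant region).
#'
#' @param g A `glcm` object from [glcm()], or a normalized probability matrix.
#' @return Named numeric vector of length 8, class `texture_params`.
#' @export
#' @examples
#' roi <- matrix(rep(3L, 64), 8, 8)
#' texture_params(glcm(roi, theta = 0, levels = 8))[["idm"]]
texture_params <- function(g) {
  p <- if (inherits(g, "glcm")) g$p else g
  if (!is.matrix(p) || nrow(p) != ncol(p))
    stop_shg("shgbof_shape_error", "GLCM must be a square matrix")
  structure(cpp_texture_params(p), class = "texture_params")
}

# Theoretical support of each parameter given the quantization depth;
# used as fixed, data-independent histogram ranges.
param_range <- function(parameter, levels) {
  n <- as.numeric(levels)
  switch(parameter,
    correlation  = c(-1, 1),
    asm          = c(0, 1),
    idm          = c(0, 1),
    contrast     = c(0, (n - 1)^2),
    entropy      = c(0, log(n^2)),
    sum_entropy  = c(0, log(2 * n - 1)),
    sum_average  = c(0, 2 * n - 2),
    sum_variance = c(0, (2 * n - 2)^2 / 4),
    stop_shg("shgbof_invalid_parameter", "unknown parameter '%s'", parameter))
}

# Fixed-range histogram: right-open bins, last bin closed, values clamped to
# the range, normalized to sum 1 (when any values exist).
hist_fixed <- function(x, lo, hi, nbins) {
  if (length(x) == 0) return(rep(0, nbins))
  x <- pmin(pmax(x, lo), hi)
  breaks <- seq(lo, hi, length.out = nbins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins) / length(x)
}

# Per-ROI parameter values for a square patch: wraps the compiled kernel and
# returns an n_roi x 32 matrix with named columns "<param>.<theta>".
roi_params_matrix <- function(patch, config = glcm_config()) {
  px <- patch_pixels(patch)
  storage.mode(px) <- "integer"
  q <- quantize_levels(px, config$levels)
  m <- cpp_roi_params(q, 8L, config$d, config$levels, config$symmetric)
  colnames(m) <- as.vector(outer(PARAMS8, THETAS,
                                 function(p, t) paste(p, t, sep = ".")))
  m
}

#' Map one texture parameter over the ROI grid of a patch
#'
#' Divides a 64x64 patch into its fixed 8x8 partition of 8x8-pixel regions of
#' interest, computes the GLCM of each ROI at orientation `theta` and returns
#' the chosen parameter as an 8x8 grid (row-major ROI order, so grid cell
#' \[a, b\] covers patch rows/cols starting at (8(a-1), 8(b-1))). Useful for
#' rendering parameter heatmaps.
#'
#' @param patch 64x64 patch (matrix or `shg_patch`).
#' @param parameter One of `"correlation"`, `"asm"`, `"contrast"`, `"idm"`,
#'   `"entropy"`, `"sum_entropy"`, `"sum_average"`, `"sum_variance"`.
#' @param theta Orientation in degrees.
#' @param config [glcm_config()].
#' @return 8x8 numeric matrix of parameter values.
#' @export
roi_param_map <- function(patch, parameter = "asm", theta = 0,
                          config = glcm_config()) {
  px <- patch_pixels(patch)
  if (nrow(px) != 64 || ncol(px) != 64)
    stop_shg("shgbof_shape_error", "patch must be 64x64, got %dx%d",
             nrow(px), ncol(px))
  parameter <- match.arg(parameter, PARAMS8)
  if (!theta %in% THETAS)
    stop_shg("shgbof_invalid_parameter", "theta must be one of 0, 45, 90, 135")
  vals <- roi_params_matrix(px, config)[, paste(parameter, theta, sep = ".")]
  matrix(vals, 8, 8, byrow = TRUE)
}
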