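#' @rdname extract_patches
#' @export
patch_pixels <- function(patch) {
  if (inherits(patch, "shg_patch")) patch$pixels else patch
}

#' Extract grid-located image patches
#'
#' Places `patch_size` x `patch_size` patches at the regular square grid with
#' step `grid_step`: origins (a g, b g) for a, b >= 0 (0-based row/col,
#' top-left origin), keeping only patches that lie fully inside the image.
#' Partial border patches are dropped, so each axis contributes
#' `floor((L - patch_size) / g) + 1` patches. Patches are returned in
#' row-major order.
#'
#' @param image 2D integer matrix of 8-bit gray levels, or `shg_image`.
#' @param patch_size Patch side in pixels (default 64, i.e. 16 um at
#'   0.25 um/px).
#' @param grid_step Grid step g in pixels; 32 or 64 in the standard protocol,
#'   but any positive integer is accepted.
#' @return List of `shg_patch` objects (fields `pixels`, `origin` (0-based
#'   row, col), `parent_id`). An image smaller than the patch gives an empty
#'   list.
#' @export
#' @examples
#' img <- matrix(0L, 128, 128)
#' length(extract_patches(img, grid_step = 64))
extract_patches <- function(image, patch_size = 64L, grid_step = 64L) {
  px <- image_pixels(image)
  id <- if (inherits(image, "shg_image")) image$image_id else NA_character_
  patch_size <- as.integer(patch_size)
  grid_step <- as.integer(grid_step)
  if (grid_step < 1L)
    stop_shg("shgbof_invalid_parameter", "grid_step must be >= 1")
  nr <- nrow(px); nc <- ncol(px)
  if (nr < patch_size || nc < patch_size) return(list())
  r0 <- seq.int(0L, nr - patch_size, by = grid_step)
  c0 <- seq.int(0L, nc - patch_size, by = grid_step)
  out <- vector("list", length(r0) * length(c0))
  k <- 1L
  for (r in r0) for (c in c0) {
    out[[k]] <- structure(
      list(pixels = px[(r + 1L):(r + patch_size),
                       (c + 1L):(c + patch_size), drop = FALSE],
           origin = c(row = r, col = c), parent_id = id),
      class = "shg_patch")
    k <- k + 1L
  }
  out
}

#' Keep patches with sufficient signal coverage
#'
#' A pixel is signal when its gray level exceeds `threshold`; a patch is kept
#' when its signal fraction is at least `min_fraction` (inclusive).
#'
#' @param patches List of patches from [extract_patches()].
#' @param threshold Gray level cutoff (default 10).
#' @param min_fraction Minimum signal fraction (default 0.25).
#' @return Filtered list of patches.
#' @export
filter_signal_patches <- function(patches, threshold = 10,
                                  min_fraction = 0.25) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop_shg("shgbof_invalid_parameter", "min_fraction must be in (0, 1]")
  keep <- vapply(patches, function(p) {
    mean(patch_pixels(p) > threshold) >= min_fraction
  }, logical(1))
  patches[keep]
}

#' Texture feature vector of a 64x64 patch
#'
#' The patch is partitioned into its 8x8 grid of 8x8-pixel ROIs; for every
#' orientation theta in (0, 45, 90, 135) each ROI yields a GLCM and the four
#' parameters correlation, ASM, contrast and IDM. The 64 per-ROI values of a
#' (parameter, theta) pair are histogrammed into 22 fixed-range bins and
#' normalized to sum 1. Blocks are concatenated parameter-major:
#' `V = (h_Cor, h_ASM, h_Con, h_IDM)` with `h = (h_0, h_45, h_90, h_135)`,
#' giving 4 x 4 x 22 = 352 elements.
#'
#' Histogram ranges are the theoretical supports (correlation \[-1, 1\]; ASM
#' and IDM \[0, 1\]; contrast \[0, (N-1)^2\] for N quantization levels), so
#' bins are data independent; right-open bins with the last bin closed.
#'
#' @param patch 64x64 patch.
#' @param config [glcm_config()].
#' @return Numeric vector of length 352.
#' @export
#' @examples
#' v <- patch_feature_vector(matrix(sample(0:255, 4096, TRUE), 64, 64))
#' length(v)
patch_feature_vector <- function(patch, config = glcm_config()) {
  px <- patch_pixels(patch)
  if (nrow(px) != 64 || ncol(px) != 64)
    stop_shg("shgbof_shape_error", "patch must be 64x64, got %dx%d",
             nrow(px), ncol(px))
  m <- roi_params_matrix(px, config)
  v <- numeric(0)
  for (param in PARAMS4) {
    rg <- param_range(param, config$levels)
    for (theta in THETAS) {
      vals <- m[, paste(param, theta, sep = ".")]
      v <- c(v, hist_fixed(vals, rg[1], rg[2], config$nbins))
    }
  }
  names(v) <- as.vector(vapply(PARAMS4, function(p)
    as.vector(vapply(THETAS, function(t)
      paste0(p, ".", t, ".b", seq_len(config$nbins)), character(config$nbins))),
    character(4 * config$nbins)))
  v
}

#' Full eight-parameter histogram profile of a patch
#'
#' Same histogram scheme as [patch_feature_vector()] extended to all eight
#' texture parameters (the classifier uses only four; the full profile
#' supports exploratory analysis and plots).
#'
#' @inheritParams patch_feature_vector
#' @return Named list of eight parameter entries, each a 4 x nbins matrix
#'   (rows = orientations 0/45/90/135, normalized to sum 1).
#' @export
full_texture_profile <- function(patch, config = glcm_config()) {
  px <- patch_pixels(patch)
  if (nrow(px) != 64 || ncol(px) != 64)
    stop_shg("shgbof_shape_error", "patch must be 64x64")
  m <- roi_params_matrix(px, config)
  out <- lapply(PARAMS8, function(param) {
    rg <- param_range(param, config$levels)
    h <- t(vapply(THETAS, function(theta)
      hist_fixed(m[, paste(param, theta, sep = ".")], rg[1], rg[2],
                 config$nbins), numeric(config$nbins)))
    rownames(h) <- paste0("theta", THETAS)
    h
  })
  names(out) <- PARAMS8
  out
}

#' Feature matrix for one image
#'
#' Extracts grid patches, drops low-signal patches and stacks the remaining
#' feature vectors.
#'
#' @param image Image matrix or `shg_image`.
#' @param grid_step Grid step in pixels.
#' @param config [glcm_config()].
#' @return Matrix with one 352-column row per kept patch; attributes
#'   `origins` (n x 2, 0-based) and `n_dropped`. Zero kept patches gives a
#'   0-row matrix.
#' @export
image_features <- function(image, grid_step = 64L, config = glcm_config()) {
  patches <- extract_patches(image, 64L, grid_step)
  kept <- filter_signal_patches(patches, config$signal_threshold,
                                config$min_signal_fraction)
  nb <- 16L * config$nbins
  if (length(kept) == 0) {
    m <- matrix(numeric(0), 0, nb)
    attr(m, "origins") <- matrix(integer(0), 0, 2)
    attr(m, "n_dropped") <- length(patches)
    return(m)
  }
  m <- t(vapply(kept, function(p) patch_feature_vector(p, config),
                numeric(nb)))
  attr(m, "origins") <- t(vapply(kept, function(p) p$origin, integer(2)))
  attr(m, "n_dropped") <- length(patches) - length(kept)
  m
}
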