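## Synthetic SHG textures. Images are simulated on the 12-bit acquisition
## scale and passed through the same 12-bit -> 8-bit conversion as real data,
## so the preprocessing path is exercised. Intensity parameters below are
## stated on the 8-bit scale and multiplied by 16 at render time.

#' Default texture parameters per tissue class
#'
#' Encodes the morphology each class shows under SHG at 0.25 um/px:
#' \describe{
#'   \item{Cartilage / Hyaline}{homogeneous moderate-intensity matrix
#'     (type II collagen emits weakly) punctured by dark circular lacunae
#'     spaced 40--80 px (10--20 um).}
#'   \item{Bone}{brighter fibrous matrix (type I collagen emits strongly)
#'     with anisotropic collagen streaks and no lacunae.}
#'   \item{Fibrous}{cartilage-like base with a surface band of thin oriented
#'     fiber bundles occupying a minority of the area, as in fibrocartilage
#'     hyperplasia.}
#' }
#'
#' @param class_name One of `"Cartilage"`, `"Hyaline"`, `"Bone"`,
#'   `"Fibrous"`.
#' @param ... Overrides for individual fields.
#' @return List of class `tissue_params`. Fields: `base_intensity` (8-bit
#'   mean gray level), `noise_sd` (additive speckle, 8-bit), `lacuna_spacing`
#'   (px between lattice sites; 60 px is 15 um at 0.25 um/px, inside the
#'   10--20 um range between neighboring lacunae), `lacuna_radius_range`
#'   (px), `lacuna_intensity`, `fiber_count` (fibers per 512-px frame side;
#'   scaled with image size so coverage is size invariant), `fiber_width_px`,
#'   `fiber_intensity`, `fiber_orientation_spread` (degrees),
#'   `band_fraction` (fraction of rows from the surface that may hold
#'   fibers), `pixel_size_um`.
#' @export
tissue_params <- function(class_name = c("Cartilage", "Hyaline", "Bone",
                                         "Fibrous"), ...) {
  class_name <- match.arg(class_name)
  base <- switch(class_name,
    Cartilage = ,
    Hyaline = list(base_intensity = 110, noise_sd = 12,
                   lacuna_spacing = 60, lacuna_radius_range = c(8, 14),
                   lacuna_intensity = 3, fiber_count = 0,
                   fiber_width_px = 0, fiber_intensity = 0,
                   fiber_orientation_spread = 0, band_fraction = 0),
    Bone = list(base_intensity = 90, noise_sd = 14,
                lacuna_spacing = Inf, lacuna_radius_range = c(0, 0),
                lacuna_intensity = 0, fiber_count = 70,
                fiber_width_px = 4, fiber_intensity = 130,
                fiber_orientation_spread = 15, band_fraction = 1),
    Fibrous = list(base_intensity = 110, noise_sd = 12,
                   lacuna_spacing = 60, lacuna_radius_range = c(8, 14),
                   lacuna_intensity = 3, fiber_count = 35,
                   fiber_width_px = 2, fiber_intensity = 110,
                   fiber_orientation_spread = 10, band_fraction = 0.3))
  p <- utils::modifyList(c(base, list(pixel_size_um = 0.25)), list(...))
  rr <- p$lacuna_radius_range
  if (is.finite(p$lacuna_spacing) && max(rr) >= p$lacuna_spacing / 2)
    stop_shg("shgbof_invalid_parameter",
             "lacuna radius must be < spacing / 2")
  if (p$base_intensity < 0 || p$base_intensity > 255)
    stop_shg("shgbof_invalid_parameter", "base_intensity outside [0, 255]")
  structure(c(p, list(class_name = class_name)), class = "tissue_params")
}

# Separable Gaussian blur with edge replication, implemented as shift-sums.
blur_gauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(m); p <- ncol(m)
  pass <- function(x, along_rows) {
    out <- 0
    for (s in (-rad):rad) {
      w <- k[s + rad + 1]
      if (along_rows) {
        idx <- pmin(pmax(seq_len(n) + s, 1L), n)
        out <- out + w * x[idx, , drop = FALSE]
      } else {
        idx <- pmin(pmax(seq_len(p) + s, 1L), p)
        out <- out + w * x[, idx, drop = FALSE]
      }
    }
    out
  }
  pass(pass(m, TRUE), FALSE)
}

# Accumulate straight fibers into an impulse map restricted to rows
# [row_min, row_max]; returns the blurred ridge field scaled to `amplitude`
# peak height for an isolated fiber.
render_fibers <- function(size, n_fibers, width_px, amplitude,
                          orientation_mean, orientation_spread,
                          row_min = 1L, row_max = size) {
  imp <- matrix(0, size, size)
  if (n_fibers == 0 || amplitude <= 0) return(imp)
  diag_len <- ceiling(1.5 * size)
  for (f in seq_len(n_fibers)) {
    ang <- (orientation_mean + rnorm(1, 0, orientation_spread)) * pi / 180
    cy <- runif(1, row_min, row_max)
    cx <- runif(1, 1, size)
    t <- seq(-diag_len / 2, diag_len / 2, by = 0.5)
    rr <- round(cy + t * sin(ang))
    cc <- round(cx + t * cos(ang))
    ok <- rr >= row_min & rr <= row_max & cc >= 1 & cc <= size
    if (!any(ok)) next
    lin <- unique((cc[ok] - 1L) * size + rr[ok])
    imp[lin] <- imp[lin] + 1
  }
  sigma <- max(width_px / 2, 0.6)
  ridge <- blur_gauss(imp, sigma)
  # unit-impulse line blurred with sd sigma has cross-section peak
  # 1 / (sigma sqrt(2 pi)); rescale so a single fiber peaks at `amplitude`
  ridge * amplitude * sigma * sqrt(2 * pi)
}

# Jittered-lattice ellipse mask; TRUE inside a lacuna.
render_lacunae <- function(size, spacing, radius_range) {
  mask <- matrix(FALSE, size, size)
  if (!is.finite(spacing)) return(mask)
  centers <- seq(spacing / 2, size, by = spacing)
  for (cy0 in centers) for (cx0 in centers) {
    cy <- cy0 + runif(1, -spacing / 5, spacing / 5)
    cx <- cx0 + runif(1, -spacing / 5, spacing / 5)
    a <- runif(1, radius_range[1], radius_range[2])        # semi-major
    b <- a * runif(1, 0.7, 1)                              # semi-minor
    phi <- runif(1, 0, pi)
    r0 <- max(1L, floor(cy - a)); r1 <- min(size, ceiling(cy + a))
    c0 <- max(1L, floor(cx - a)); c1 <- min(size, ceiling(cx + a))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    dy <- outer(rr - cy, rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - cx)
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    mask[rr, cc] <- mask[rr, cc] | (u^2 / a^2 + v^2 / b^2 <= 1)
  }
  mask
}

# Shared rendering core: background + fibers + lacunae + speckle, simulated
# at 12-bit and converted to 8-bit through the standard path.
render_tissue <- function(size, params, seed) {
  set.seed(seed)
  p <- params
  field <- matrix(p$base_intensity, size, size)
  # low-frequency illumination/matrix variation, ~8% of base
  lf <- blur_gauss(matrix(rnorm(size * size), size, size), size / 16)
  field <- field * (1 + lf / max(abs(range(lf)), 1e-12) * 0.08)
  if (p$fiber_count > 0) {
    band_rows <- max(1L, round(size * p$band_fraction))
    orientation_mean <- if (p$band_fraction < 1) 0 else runif(1, 0, 180)
    # fiber_count is stated per 512-px frame; scale linearly with the side
    # so area coverage (count x length / area) is size invariant
    n_fib <- max(1L, round(p$fiber_count * size / 512))
    field <- field + render_fibers(size, n_fib, p$fiber_width_px,
                                   p$fiber_intensity, orientation_mean,
                                   p$fiber_orientation_spread,
                                   row_min = 1L, row_max = band_rows)
  }
  lac <- render_lacunae(size, p$lacuna_spacing, p$lacuna_radius_range)
  field[lac] <- p$lacuna_intensity
  if (p$noise_sd > 0)
    field <- field + rnorm(size * size, 0, p$noise_sd)
  raw12 <- matrix(as.integer(pmin(pmax(round(field * 16), 0), 4095)),
                  size, size)
  attr(raw12, "lacuna_mask") <- lac
  raw12
}

#' Generate a synthetic tissue image
#'
#' `gen_cartilage_image()`, `gen_bone_image()` and `gen_fibrous_image()`
#' draw one 8-bit image of the requested class from the stochastic texture
#' model in [tissue_params()]. Generation is byte-identical for a fixed
#' (params, seed) pair: two different seeds give different images with the
#' same summary statistics.
#'
#' @param size Image side in pixels (default 512).
#' @param params A `tissue_params` object (class-appropriate default).
#' @param seed Integer RNG seed.
#' @return `shg_image` (12-bit source, converted to 8-bit).
#' @export
#' @examples
#' img <- gen_cartilage_image(size = 128, seed = 1)
#' range(img$pixels)
gen_cartilage_image <- function(size = 512L, params = tissue_params("Cartilage"),
                                seed = 1L) {
  raw <- render_tissue(size, params, seed)
  out <- convert_12_to_8bit(raw, pixel_size_um = params$pixel_size_um,
                            image_id = sprintf("%s_s%d", params$class_name, seed))
  attr(out, "lacuna_mask") <- attr(raw, "lacuna_mask")
  out
}

#' @rdname gen_cartilage_image
#' @export
gen_bone_image <- function(size = 512L, params = tissue_params("Bone"),
                           seed = 1L) {
  gen_cartilage_image(size, params, seed)
}

#' @rdname gen_cartilage_image
#' @export
gen_fibrous_image <- function(size = 512L, params = tissue_params("Fibrous"),
                              seed = 1L) {
  gen_cartilage_image(size, params, seed)
}

#' Generate a labeled synthetic image set
#'
#' Draws `n_per_class` images per class with per-image seeds derived from
#' `seed`. Optionally writes 8-bit TIFFs plus a CSV manifest (filename,
#' class, seed) that round-trips through [read_gray()] /
#' [load_dataset()].
#'
#' @param n_per_class Images per class.
#' @param classes Character vector of class names understood by
#'   [tissue_params()].
#' @param size Image side (default 512).
#' @param seed Master seed.
#' @param dir Output directory for TIFFs + manifest, or `NULL` (default) to
#'   keep the set in memory only.
#' @param params Optional named list of `tissue_params` overriding the
#'   class defaults.
#' @return `shg_image_set`: list with `images`, `labels` (factor with levels
#'   in the order of `classes`), `ids`, and `manifest` (data.frame).
#' @export
gen_dataset <- function(n_per_class, classes = c("Cartilage", "Bone"),
                        size = 512L, seed = 1L, dir = NULL, params = NULL) {
  images <- list(); labels <- character(0); ids <- character(0)
  rows <- list()
  for (cl in classes) {
    p <- if (!is.null(params) && !is.null(params[[cl]])) params[[cl]]
         else tissue_params(cl)
    for (i in seq_len(n_per_class)) {
      s <- derive_seed(seed, paste0(cl, i))
      img <- gen_cartilage_image(size, p, s)
      id <- sprintf("%s_%03d", cl, i)
      img$image_id <- id
      images[[length(images) + 1]] <- img
      labels <- c(labels, cl); ids <- c(ids, id)
      fn <- paste0(id, ".tif")
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        write_gray(img, file.path(dir, fn))
      }
      rows[[length(rows) + 1]] <- data.frame(filename = fn, class = cl,
                                             seed = s, size = size)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(list(images = images,
                 labels = factor(labels, levels = classes), ids = ids,
                 manifest = manifest),
            class = "shg_image_set")
}

#' Load a labeled image set from a manifest directory
#'
#' Reads the `manifest.csv` + image files written by [gen_dataset()] (or any
#' directory following the same layout) back into an `shg_image_set`.
#'
#' @param dir Directory containing `manifest.csv`.
#' @return `shg_image_set`.
#' @export
load_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  images <- lapply(seq_len(nrow(manifest)), function(i)
    read_gray(file.path(dir, manifest$filename[i]),
              image_id = tools::file_path_sans_ext(manifest$filename[i])))
  structure(list(images = images,
                 labels = factor(manifest$class,
                                 levels = unique(manifest$class)),
                 ids = tools::file_path_sans_ext(manifest$filename),
                 manifest = manifest),
            class = "shg_image_set")
}

#' @export
print.shg_image_set <- function(x, ...) {
  cat(sprintf("<shg_image_set: %d images; %s>\n", length(x$images),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}
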