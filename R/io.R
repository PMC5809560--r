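#' 8-bit grayscale image container
#'
#' Thin wrapper around an integer pixel matrix carrying the metadata the
#' pipeline needs. Coordinates are (row, col), 0-based, top-left origin;
#' crops use half-open intervals.
#'
#' @param pixels Integer matrix with values in \[0, 255\].
#' @param pixel_size_um Microns per pixel (default 0.25, the acquisition
#'   geometry for which a 64 px patch covers 16 um).
#' @param source_bit_depth 8 or 12.
#' @param image_id Identifier string.
#' @return Object of class `shg_image`.
#' @export
shg_image <- function(pixels, pixel_size_um = 0.25, source_bit_depth = 8L,
                      image_id = NA_character_) {
  if (!is.matrix(pixels)) stop_shg("shgbof_shape_error", "pixels must be a matrix")
  if (any(pixels < 0 | pixels > 255))
    stop_shg("shgbof_range_error", "8-bit gray levels must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 source_bit_depth = as.integer(source_bit_depth),
                 image_id = image_id),
            class = "shg_image")
}

#' @rdname shg_image
#' @param image An `shg_image` or plain matrix.
#' @export
image_pixels <- function(image) {
  if (inherits(image, "shg_image")) image$pixels else image
}

#' @export
print.shg_image <- function(x, ...) {
  cat(sprintf("<shg_image %s: %d x %d px, %.3g um/px, %d-bit source>\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$source_bit_depth))
  invisible(x)
}

#' Convert a 12-bit image to 8-bit
#'
#' Acquisition records 12-bit intensities; texture analysis runs on 8-bit.
#' The default conversion is `floor(v / 16)`, order preserving. An optional
#' percentile-rescale mode maps \[0, q-th percentile\] linearly onto
#' \[0, 255\] (off by default).
#'
#' @param raw Matrix of 12-bit values in \[0, 4095\].
#' @param rescale_percentile Numeric in (0, 100\] enabling percentile
#'   rescaling, or `NULL` (default) for plain floor division.
#' @param ... Passed to [shg_image()].
#' @return `shg_image` with `source_bit_depth = 12`.
#' @export
#' @examples
#' convert_12_to_8bit(matrix(c(15L, 16L, 4095L, 0L), 2, 2))$pixels
convert_12_to_8bit <- function(raw, rescale_percentile = NULL, ...) {
  if (any(raw < 0 | raw > 4095))
    stop_shg("shgbof_range_error", "12-bit values must lie in [0, 4095]")
  if (is.null(rescale_percentile)) {
    px <- matrix(as.integer(raw %/% 16L), nrow = nrow(raw))
  } else {
    top <- stats::quantile(raw, rescale_percentile / 100, names = FALSE)
    px <- matrix(pmin(255L, as.integer(floor(raw / max(top, 1) * 255))),
                 nrow = nrow(raw))
  }
  shg_image(px, source_bit_depth = 12L, ...)
}

#' Crop sub-images
#'
#' Either divides the image into a regular block grid (`regular_blocks`,
#' requiring both dimensions to be divisible by `size`; a 2048x2048 frame
#' yields 16 crops of 512x512) or cuts explicitly listed regions
#' (`manual_rois`). Manual ROIs are bounds-checked and never resampled.
#'
#' @param image `shg_image` or matrix.
#' @param size Square crop side for block mode (default 512).
#' @param mode `"regular_blocks"` or `"manual_rois"`.
#' @param rois For manual mode: matrix/data.frame with columns (row, col)
#'   giving 0-based top-left origins of `size` x `size` crops.
#' @return List of `shg_image` crops, row-major, ids suffixed with the crop
#'   origin.
#' @export
crop_subimages <- function(image, size = 512L,
                           mode = c("regular_blocks", "manual_rois"),
                           rois = NULL) {
  mode <- match.arg(mode)
  px <- image_pixels(image)
  meta <- if (inherits(image, "shg_image")) image else shg_image(px)
  size <- as.integer(size)
  if (mode == "regular_blocks") {
    if (nrow(px) %% size != 0 || ncol(px) %% size != 0)
      stop_shg("shgbof_shape_error",
               "image %dx%d not divisible into %dx%d blocks",
               nrow(px), ncol(px), size, size)
    origins <- expand.grid(row = seq.int(0L, nrow(px) - size, by = size),
                           col = seq.int(0L, ncol(px) - size, by = size))
    origins <- origins[order(origins$row, origins$col), ]
  } else {
    if (is.null(rois)) stop_shg("shgbof_invalid_parameter",
                                "manual_rois mode requires `rois`")
    origins <- as.data.frame(rois)
    names(origins)[1:2] <- c("row", "col")
    bad <- origins$row < 0 | origins$col < 0 |
      origins$row + size > nrow(px) | origins$col + size > ncol(px)
    if (any(bad))
      stop_shg("shgbof_shape_error", "ROI extends outside the image")
  }
  lapply(seq_len(nrow(origins)), function(i) {
    r <- origins$row[i]; c <- origins$col[i]
    shg_image(px[(r + 1):(r + size), (c + 1):(c + size), drop = FALSE],
              pixel_size_um = meta$pixel_size_um,
              source_bit_depth = meta$source_bit_depth,
              image_id = paste0(meta$image_id, "_r", r, "c", c))
  })
}

#' Keep images with sufficient signal coverage
#'
#' Image-level analogue of [filter_signal_patches()] with one deliberate
#' difference: an image is kept only when *more than* `min_fraction` of its
#' area is signal (strict inequality), so an image with exactly 25% signal is
#' dropped.
#'
#' @param images List of images.
#' @param threshold Gray level cutoff (default 10).
#' @param min_fraction Signal fraction that must be exceeded (default 0.25).
#' @return Filtered list.
#' @export
filter_signal_images <- function(images, threshold = 10,
                                 min_fraction = 0.25) {
  keep <- vapply(images, function(im) {
    mean(image_pixels(im) > threshold) > min_fraction
  }, logical(1))
  images[keep]
}

## ---- grayscale TIFF / PGM codecs -------------------------------------------
## Minimal baseline TIFF: little-endian, uncompressed, single strip, one
## sample per pixel, 8- or 16-bit. No R TIFF package is available in the
## deployment environment, so the subset needed for round-tripping the
## pipeline's own images (and files written by common scientific writers in
## that subset) is implemented here.

tiff_write_gray <- function(pixels, path, bits = 8L) {
  stopifnot(bits %in% c(8L, 16L))
  nr <- nrow(pixels); nc <- ncol(pixels)
  con <- file(path, "wb"); on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)     # header, IFD at byte 8
  entries <- list( # tag, type (3 short / 4 long), value
    c(256L, 3L, nc),                 # ImageWidth
    c(257L, 3L, nr),                 # ImageLength
    c(258L, 3L, bits),               # BitsPerSample
    c(259L, 3L, 1L),                 # Compression = none
    c(262L, 3L, 1L),                 # Photometric = BlackIsZero
    c(273L, 4L, 0L),                 # StripOffsets (patched below)
    c(277L, 3L, 1L),                 # SamplesPerPixel
    c(278L, 3L, nr),                 # RowsPerStrip
    c(279L, 4L, nr * nc * (bits %/% 8L)) # StripByteCounts
  )
  n <- length(entries)
  data_off <- 8L + 2L + n * 12L + 4L
  entries[[6]][3] <- data_off
  w2(n)
  for (e in entries) {
    w2(e[1]); w2(e[2]); w4(1L)
    if (e[2] == 3L) { w2(e[3]); w2(0L) } else w4(e[3])
  }
  w4(0L)  # no next IFD
  # TIFF stores rows contiguously: transpose column-major R matrix
  v <- as.integer(t(pixels))
  writeBin(v, con, size = bits %/% 8L, endian = "little")
  invisible(path)
}

tiff_read_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop_shg("shgbof_io_error", "not a TIFF file: %s", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop_shg("shgbof_io_error", "not a TIFF file: %s", path)
  rd <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = size == 4, endian = endian)
  if (rd(2, 2) != 42L) stop_shg("shgbof_io_error", "not a TIFF file: %s", path)
  ifd <- rd(4, 4)
  n <- rd(ifd, 2)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- rd(e, 2); type <- rd(e + 2, 2); count <- rd(e + 4, 4)
    val <- if (type == 3L) rd(e + 8, 2) else rd(e + 8, 4)
    if (count > 1L) { # value is an offset to an array
      off <- rd(e + 8, 4)
      val <- rd(off, if (type == 3L) 2L else 4L, count)
    }
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop_shg("shgbof_io_error",
                                     "TIFF missing tag %d", tag)
      default
    } else v
  }
  nc <- need(256); nr <- need(257); bits <- need(258, 8L)
  if (need(259, 1L) != 1L)
    stop_shg("shgbof_io_error", "only uncompressed TIFF is supported")
  if (need(277, 1L) != 1L)
    stop_shg("shgbof_io_error", "only single-sample grayscale TIFF is supported")
  offs <- need(273); counts <- need(279, nr * nc * (bits %/% 8L))
  bsz <- bits %/% 8L
  vals <- integer(0)
  for (s in seq_along(offs)) {
    npx <- counts[s] %/% bsz
    seg <- readBin(raw[(offs[s] + 1):(offs[s] + counts[s])], "integer",
                   n = npx, size = bsz, signed = FALSE, endian = endian)
    vals <- c(vals, seg)
  }
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

pgm_write_gray <- function(pixels, path, ascii = FALSE) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (ascii) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P2", paste(nc, nr), "255"), con)
    write(t(pixels), con, ncolumns = nc)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", nc, nr), con, eos = NULL)
    writeBin(as.raw(as.integer(t(pixels))), con)
  }
  invisible(path)
}

pgm_read_gray <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5"))
    stop_shg("shgbof_io_error", "not a PGM file: %s", path)
  tok <- function() { # whitespace/comment-delimited integer token
    repeat {
      ch <- readChar(con, 1)
      if (ch == "#") repeat { ch <- readChar(con, 1); if (ch == "\n") break }
      if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1)
      if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    as.integer(out)
  }
  nc <- tok(); nr <- tok(); maxv <- tok()
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", nr * nc))
  } else {
    vals <- integer(nr * nc)
    for (i in seq_len(nr * nc)) vals[i] <- tok()
  }
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Read and write grayscale images
#'
#' Format chosen by extension: `.tif`/`.tiff` (baseline uncompressed
#' grayscale TIFF, 8- or 16-bit) or `.pgm` (binary P5, or ASCII P2 with
#' `ascii = TRUE`). Write-then-read reproduces pixels exactly.
#'
#' @param path File path.
#' @param image `shg_image` or matrix (for writing).
#' @param bits Bit depth for TIFF output: 8 (default) or 16 (used to store
#'   12-bit raw data).
#' @param ascii Write ASCII PGM (text; useful for version-controlled
#'   fixtures).
#' @param ... Metadata passed to [shg_image()] on read.
#' @return `read_gray()` returns an `shg_image`; `write_gray()` returns the
#'   path invisibly.
#' @export
read_gray <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff_read_gray(path),
    pgm = pgm_read_gray(path),
    stop_shg("shgbof_io_error", "unsupported image format: .%s", ext))
  args <- list(...)
  if (max(px) > 255) { # 16-bit container holding 12-bit data
    return(do.call(convert_12_to_8bit, c(list(raw = px), args)))
  }
  if (is.null(args$image_id))
    args$image_id <- tools::file_path_sans_ext(basename(path))
  do.call(shg_image, c(list(pixels = px), args))
}

#' @rdname read_gray
#' @export
write_gray <- function(image, path, bits = 8L, ascii = FALSE) {
  px <- image_pixels(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff_write_gray(px, path, bits = as.integer(bits)),
    pgm = pgm_write_gray(px, path, ascii = ascii),
    stop_shg("shgbof_io_error", "unsupported image format: .%s", ext))
  invisible(path)
}
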