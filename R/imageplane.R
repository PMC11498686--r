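#' Single-channel image plane
#'
#' The universal currency of the fusion pipeline: a real-valued matrix with
#' intensities in \[0, 1\], together with the bit depth of the file it came
#' from and free-form provenance tags. Colour inputs are reduced to luminance
#' at read time (Rec.601 weights); their chroma planes are kept in `meta` so
#' [chroma_reinject()] can recompose a colour result.
#'
#' @param pixels Numeric matrix with values in \[0, 1\].
#' @param bit_depth Source bit depth, 8 or 16.
#' @param meta Named list of provenance tags.
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(pixels, bit_depth = 8L, meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_medfuse("medfuse_validation", "pixels must be a numeric matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop_medfuse("medfuse_validation",
                 sprintf("image must be at least 16x16 (got %dx%d)",
                         nrow(pixels), ncol(pixels)))
  if (anyNA(pixels) || min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop_medfuse("medfuse_validation", "pixel values must lie in [0, 1]")
  if (!bit_depth %in% c(8L, 16L))
    stop_medfuse("medfuse_param", "bit_depth must be 8 or 16")
  structure(list(pixels = clip01(pixels),
                 height = nrow(pixels), width = ncol(pixels),
                 source_bit_depth = as.integer(bit_depth), meta = meta),
            class = "image_plane")
}

#' Coerce to an image plane
#'
#' @param x An `image_plane` or a numeric matrix in \[0, 1\].
#' @param ... Passed to [image_plane()] for matrix input.
#' @return An `image_plane`.
#' @export
as_image_plane <- function(x, ...) {
  if (inherits(x, "image_plane")) return(x)
  image_plane(x, ...)
}

# Extract the pixel matrix from an image_plane or pass a matrix through.
# Most numeric internals work on plain matrices and are documented to accept
# either form.
px <- function(x) {
  if (inherits(x, "image_plane")) x$pixels else x
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d, %d-bit source, range [%.4f, %.4f]\n",
              x$height, x$width, x$source_bit_depth,
              min(x$pixels), max(x$pixels)))
  if (!is.null(x$meta$path)) cat("  path:", x$meta$path, "\n")
  if (!is.null(x$meta$chroma)) cat("  chroma planes retained\n")
  invisible(x)
}

#' @export
plot.image_plane <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = x$height / x$width)
  graphics::rasterImage(grDevices::as.raster(x$pixels), 0, 0, 1, 1)
  invisible(x)
}

rec601_luma <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

png_bit_depth <- function(path) {
  hdr <- try(readBin(path, "raw", n = 25L), silent = TRUE)
  if (inherits(hdr, "try-error") || length(hdr) < 25L) return(8L)
  d <- as.integer(hdr[25])
  if (d == 16L) 16L else 8L
}

#' Read an image file as a canonical luminance plane
#'
#' PNG and TIFF files are supported, 8- or 16-bit, greyscale or colour.
#' Integer intensities are divided by `2^depth - 1`, so a full-scale pixel
#' maps to exactly 1. Colour images are reduced with the Rec.601 luma weights
#' (0.299, 0.587, 0.114); the Cb/Cr chroma planes are stored in
#' `meta$chroma` for later recomposition.
#'
#' @param path Path to a PNG or TIFF image.
#' @return An [image_plane()].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop_medfuse("medfuse_format", sprintf("cannot read image: '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = try(png::readPNG(path), silent = TRUE),
    tif  = ,
    tiff = try(tiff::readTIFF(path, info = TRUE), silent = TRUE),
    jpg  = ,
    jpeg = stop_medfuse("medfuse_format",
                        sprintf("'%s': JPEG input is not supported; convert to PNG or TIFF", path)),
    stop_medfuse("medfuse_format",
                 sprintf("'%s': unrecognised image extension '%s'", path, ext))
  )
  if (inherits(arr, "try-error"))
    stop_medfuse("medfuse_format", sprintf("failed to decode image file '%s'", path))
  if (length(arr) == 0L)
    stop_medfuse("medfuse_validation", sprintf("'%s' is a zero-sized image", path))
  depth <- if (ext == "png") png_bit_depth(path) else {
    bps <- attr(arr, "bits.per.sample")
    if (!is.null(bps) && bps == 16L) 16L else 8L
  }
  meta <- list(path = path)
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) {
    y <- rec601_luma(arr)
    # JFIF-style chroma, centred at zero
    meta$chroma <- list(cb = 0.5 * (arr[, , 3] - y) / (1 - 0.114),
                        cr = 0.5 * (arr[, , 1] - y) / (1 - 0.299))
    meta$color <- TRUE
  } else {
    y <- if (length(dim(arr)) == 3L) arr[, , 1] else arr
    meta$color <- FALSE
  }
  image_plane(clip01(y), bit_depth = depth, meta = meta)
}

#' Write an image plane to disk
#'
#' Quantisation is round-half-to-even (R's `round`), 8-bit PNG by default.
#'
#' @param img An `image_plane` or numeric matrix in \[0, 1\].
#' @param path Output path; format chosen by extension (.png or .tif/.tiff).
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  x <- clip01(px(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") bit_depth <- 8L  # PNG output is written as 8-bit
  scale <- 2^bit_depth - 1
  q <- round(x * scale) / scale
  if (ext == "png") {
    png::writePNG(q, path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = as.integer(bit_depth))
  } else {
    stop_medfuse("medfuse_format", sprintf("unsupported output extension '%s'", ext))
  }
  invisible(path)
}
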