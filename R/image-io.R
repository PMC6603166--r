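#' Construct a stain image
#'
#' The unit of all pixel-space work in the package: an H x W x 3 array of
#' intensities in `[0, 1]`. Grayscale sources are stored with all three
#' channels equal so that any image can be fed to a 3-channel backbone.
#'
#' @param pixels numeric H x W x 3 array (or H x W matrix, replicated to three
#'   equal channels) with finite values in `[0, 1]`.
#' @param source_id opaque label carried along for bookkeeping.
#' @return An object of class `stain_image`: the pixel array with attributes
#'   `source_id`.
#' @examples
#' img <- stain_image(array(runif(12), dim = c(2, 2, 3)))
#' dim(img)
#' @export
stain_image <- function(pixels, source_id = "image") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array (or an H x W matrix).",
          class = "hestain_format_error")
  }
  if (!all(is.finite(pixels))) {
    abort("image intensities must all be finite", class = "hestain_numeric_error")
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    abort("image intensities must lie in [0, 1]", class = "hestain_domain_error")
  }
  structure(pixels, source_id = as.character(source_id), class = "stain_image")
}

is_stain_image <- function(x) inherits(x, "stain_image")

#' @export
print.stain_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<stain_image> %d x %d px, 3 channels, source '%s'\n",
              d[1], d[2], attr(x, "source_id")))
  cat(sprintf("  intensity range [%.3f, %.3f]\n", min(x), max(x)))
  invisible(x)
}

image_height <- function(img) dim(img)[1]
image_width  <- function(img) dim(img)[2]

#' Read a PNG or TIFF image
#'
#' Reads an 8- or 16-bit, 1- or 3-channel raster file and rescales intensities
#' to `[0, 1]`; single-channel inputs are replicated to three equal channels.
#' An alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.tif`, or `.tiff` file.
#' @param source_id label stored on the result; defaults to the file name.
#' @return A [stain_image()].
#' @export
load_image <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read image: no such file '%s'", path),
          class = "hestain_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format '.%s' for '%s' (PNG or TIFF expected)",
                  ext, path), class = "hestain_format_error")
  )
  # readPNG/readTIFF already rescale 8/16-bit samples to [0, 1]
  if (is.matrix(px)) {
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  } else if (length(dim(px)) == 3L && dim(px)[3] %in% c(2L, 4L)) {
    px <- px[, , seq_len(dim(px)[3] - 1L), drop = FALSE]  # drop alpha
    if (dim(px)[3] == 1L) px <- array(rep(px, 3L), dim = c(dim(px)[1:2], 3L))
  }
  if (length(dim(px)) != 3L || !dim(px)[3] %in% c(3L)) {
    abort(sprintf("unsupported channel layout in '%s' (%s channels)",
                  path, paste(dim(px), collapse = "x")),
          class = "hestain_format_error")
  }
  stain_image(px, source_id = source_id)
}

#' Write an image as 8-bit PNG
#'
#' Intensities are clamped to `[0, 1]` and quantized with
#' round-half-away-from-zero to 8 bits, so `load_image(save_image(x))`
#' round-trips within 1/255 per channel.
#'
#' @param img a [stain_image()].
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(is_stain_image(img) || (is.array(img) && length(dim(img)) == 3L))
  if (!dir.exists(dirname(path))) {
    abort(sprintf("cannot write image: no such directory '%s'", dirname(path)),
          class = "hestain_io_error")
  }
  px <- pmin(pmax(unclass(img), 0), 1)
  # round half away from zero, then back to [0,1] so writePNG quantizes exactly
  bytes <- floor(px * 255 + 0.5)
  png::writePNG(bytes / 255, target = path)
  invisible(path)
}

#' Center-crop an image
#'
#' Keeps the central `fraction` of each dimension. Output dimensions are
#' `round(fraction * dim)`; when the crop cannot be perfectly centered the
#' extra row/column of slack is placed on the bottom/right.
#'
#' @param img a [stain_image()].
#' @param fraction fraction of each dimension to keep, in `(0, 1]`.
#' @return A [stain_image()] with the cropped pixels.
#' @export
center_crop <- function(img, fraction = 0.5) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single number in (0, 1]",
          class = "hestain_domain_error")
  }
  h <- image_height(img); w <- image_width(img)
  oh <- max(1L, round(fraction * h)); ow <- max(1L, round(fraction * w))
  r0 <- floor((h - oh) / 2)  # top offset; slack goes to the bottom
  c0 <- floor((w - ow) / 2)
  stain_image(unclass(img)[r0 + seq_len(oh), c0 + seq_len(ow), , drop = FALSE],
              source_id = attr(img, "source_id"))
}

#' Resize an image to given dimensions
#'
#' Bilinear resampling (used internally to bring the style image to the
#' content image's working resolution).
#'
#' @param img a [stain_image()].
#' @param height,width target dimensions in pixels.
#' @return A [stain_image()].
#' @export
resize_image <- function(img, height, width) {
  h <- image_height(img); w <- image_width(img)
  if (h == height && w == width) return(img)
  # EBImage uses x (= column) first
  eb <- EBImage::Image(aperm(unclass(img), c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(eb, w = width, h = height)
  px <- aperm(EBImage::imageData(out), c(2, 1, 3))
  stain_image(pmin(pmax(px, 0), 1), source_id = attr(img, "source_id"))
}

#' @method autoplot stain_image
#' @export
autoplot.stain_image <- function(object, ...) {
  d <- dim(object)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  px <- unclass(object)
  df$fill <- grDevices::rgb(px[, , 1][as.matrix(df[, 1:2])],
                            px[, , 2][as.matrix(df[, 1:2])],
                            px[, , 3][as.matrix(df[, 1:2])])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
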