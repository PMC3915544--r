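#' Construct a color image
#'
#' A `color_image` is an H x W x 3 numeric raster with a declared value scale
#' and a colorspace tag. All floating-point computation in the package happens
#' on the `unit` scale; 8-bit integer data is converted at the boundary by
#' [normalize_rgb()].
#'
#' @param pixels numeric H x W x 3 array (R, G, B along the third dimension).
#' @param scale `"eight_bit"` for integer values in \[0, 255\], `"unit"` for
#'   real values in \[0, 1\].
#' @param colorspace `"sRGB_nonlinear"` for gamma-encoded device RGB (the
#'   state of any camera file), `"sRGB_linear"` after [srgb_linearize()].
#' @return An object of class `color_image`.
#' @examples
#' img <- color_image(array(128, c(2, 2, 3)))
#' normalize_rgb(img)
#' @export
color_image <- function(pixels, scale = c("eight_bit", "unit"),
                        colorspace = c("sRGB_nonlinear", "sRGB_linear")) {
  scale <- match.arg(scale)
  colorspace <- match.arg(colorspace)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    ag_stop("`pixels` must be an H x W x 3 array", "applegrader_shape_error")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    ag_stop("image must have at least one row and one column",
            "applegrader_shape_error")
  if (!is.numeric(pixels) || anyNA(pixels))
    ag_stop("`pixels` must be numeric and free of NA", "applegrader_value_error")
  lim <- if (scale == "eight_bit") c(0, 255) else c(0, 1)
  rng <- range(pixels)
  if (rng[1] < lim[1] || rng[2] > lim[2])
    ag_stop(sprintf("pixel values [%g, %g] outside declared %s scale [%g, %g]",
                    rng[1], rng[2], scale, lim[1], lim[2]),
            "applegrader_scale_error")
  structure(list(pixels = pixels, scale = scale, colorspace = colorspace),
            class = "color_image")
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<color_image> %d x %d, scale=%s, colorspace=%s\n",
              d[1], d[2], x$scale, x$colorspace))
  invisible(x)
}

#' @export
dim.color_image <- function(x) dim(x$pixels)

#' Rescale an 8-bit image to the unit interval
#'
#' Divides every channel by 255 and retags the scale, leaving the gamma
#' encoding untouched. Rejects images whose declared scale is not `eight_bit`.
#'
#' @param image a [color_image()] on the `eight_bit` scale.
#' @return A `color_image` on the `unit` scale.
#' @export
normalize_rgb <- function(image) {
  stopifnot(inherits(image, "color_image"))
  if (image$scale != "eight_bit")
    ag_stop("normalize_rgb() expects an eight_bit image",
            "applegrader_scale_error")
  color_image(image$pixels / 255, scale = "unit", colorspace = image$colorspace)
}

#' Read an RGB image file as a color_image
#'
#' Supports PNG (always), and TIFF/JPEG when the `tiff`/`jpeg` packages are
#' available. Gray images are replicated to three channels; an alpha channel
#' is dropped. Values are quantized to the 8-bit scale, the native precision
#' of the grading pipeline.
#'
#' @param path file path; format inferred from the extension.
#' @return A `color_image` on the `eight_bit` scale.
#' @export
read_color_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        ag_stop("package 'tiff' required to read TIFF", "applegrader_io_error")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        ag_stop("package 'jpeg' required to read JPEG", "applegrader_io_error")
      jpeg::readJPEG(path)
    },
    ag_stop(sprintf("unsupported image format '.%s'", ext),
            "applegrader_io_error")
  )
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  color_image(round(px * 255), scale = "eight_bit")
}

#' Write a color_image to a PNG file
#'
#' @param image a [color_image()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_color_image <- function(image, path) {
  stopifnot(inherits(image, "color_image"))
  px <- image$pixels
  if (image$scale == "eight_bit") px <- px / 255
  png::writePNG(px, path)
  invisible(path)
}
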