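#' Load a scanned stain image from PNG or TIFF
#'
#' Reads an RGB raster and returns it as 8-bit intensities. 16-bit inputs
#' are rescaled to 8-bit by `round(x / 65535 * 255)` (readers return values
#' on \[0, 1\], so the mapping is `round(v * 255)`). A fully opaque alpha
#' channel is dropped; grayscale images, images with a varying alpha
#' channel, and unreadable files raise a `format_error`.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A [stain_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      abort_format(sprintf("unsupported image format '.%s'", ext))
    ),
    error = function(e) {
      if (inherits(e, "sicklestain_error")) stop(e)
      abort_format(sprintf("cannot read '%s': %s", path, conditionMessage(e)))
    }
  )
  if (length(dim(arr)) == 2L)
    abort_format("grayscale image: 3 RGB channels required")
  if (dim(arr)[3] == 4L) {
    alpha <- arr[, , 4]
    if (any(alpha != alpha[1]))
      abort_format("image has a varying alpha channel")
    arr <- arr[, , 1:3, drop = FALSE]
  }
  if (dim(arr)[3] != 3L)
    abort_format(sprintf("expected 3 channels, found %d", dim(arr)[3]))
  stain_image(round(arr * 255), metadata = list(path = path))
}

#' Write a stain image as an 8-bit RGB PNG
#'
#' @param image a [stain_image()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_stain_png <- function(image, path) {
  stopifnot(inherits(image, "stain_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}
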