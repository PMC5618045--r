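#' Compute the S-index of a segmented blood stain
#'
#' The S-index quantifies how dark and well-defined a stain's center spot is
#' relative to its peripheral ring: it is the quotient of the mean red color
#' intensity of the center-spot pixels and the mean red color intensity of
#' the ring pixels, where red color intensity is `255 - B` and `B` is the
#' blue channel of the 8-bit RGB image. Only the blue channel enters the
#' computation; red and green are ignored entirely.
#'
#' @param image a [stain_image()].
#' @param seg a [stain_segmentation()] whose masks match the image.
#' @return An object of class `s_index_result`: list with `s_index`,
#'   `center_mean_red` and `ring_mean_red`.
#' @examples
#' r <- render_stain(stain_render_spec(80, "MS", noise_sd = 0))
#' s_index(r$image, r$truth)
#' @export
s_index <- function(image, seg) {
  stopifnot(inherits(image, "stain_image"), inherits(seg, "stain_segmentation"))
  if (!identical(dim(image$pixels)[1:2], dim(seg$center_mask)))
    abort_validation("segmentation masks do not match image dimensions")
  red <- 255 - image$pixels[, , 3]
  center_mean <- mean(red[seg$center_mask])
  ring_mean <- mean(red[seg$ring_mask])
  if (!is.finite(ring_mean) || ring_mean <= 0)
    stop_sicklestain("degenerate_input", "ring mean red intensity is zero (pure-white ring)")
  structure(list(s_index = center_mean / ring_mean,
                 center_mean_red = center_mean,
                 ring_mean_red = ring_mean),
            class = "s_index_result")
}

#' @export
print.s_index_result <- function(x, ...) {
  cat(sprintf("S-index %.3f (center mean red %.1f / ring mean red %.1f)\n",
              x$s_index, x$center_mean_red, x$ring_mean_red))
  invisible(x)
}

#' Segment and score every stain image in a directory
#'
#' Processes images in filename order. Stains that fail to segment are
#' reported as flagged rows (flag = the error's condition class) with `NA`
#' values rather than dropped.
#'
#' @param image_dir directory containing `.png`/`.tif`/`.tiff` images.
#' @param output_csv optional path; when given, the table is also written as
#'   CSV with columns `stain_id`, `s_index`, `center_mean_red`,
#'   `ring_mean_red`, `flag`.
#' @param ... passed to [segment_stain()].
#' @return A data.frame, one row per image.
#' @export
analyze_batch <- function(image_dir, output_csv = NULL, ...) {
  files <- sort(list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  if (length(files) == 0L)
    abort_validation(sprintf("no images found in '%s'", image_dir))
  rows <- lapply(files, function(f) {
    res <- tryCatch({
      img <- load_image(file.path(image_dir, f))
      si <- s_index(img, segment_stain(img, ...))
      data.frame(stain_id = f, s_index = si$s_index,
                 center_mean_red = si$center_mean_red,
                 ring_mean_red = si$ring_mean_red, flag = "ok")
    }, sicklestain_error = function(e) {
      data.frame(stain_id = f, s_index = NA_real_,
                 center_mean_red = NA_real_, ring_mean_red = NA_real_,
                 flag = class(e)[1])
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(output_csv)) utils::write.csv(out, output_csv, row.names = FALSE)
  out
}

#' Intersection-over-union of two segmentation masks
#'
#' @param a,b logical matrices of identical dimensions.
#' @return IoU in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}
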