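# Run code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Construct a blood stain image object
#'
#' @param pixels H x W x 3 array of 8-bit intensities (R, G, B channels).
#' @param resolution optional pixels-per-mm scalar.
#' @param metadata free-form provenance list (true \%HbS, formulation, ...).
#' @return An object of class `stain_image`.
#' @export
stain_image <- function(pixels, resolution = NULL, metadata = list()) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    abort_format("pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 32L || dim(pixels)[2] < 32L)
    abort_format("image must be at least 32 x 32 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    abort_format("pixel intensities must lie in [0, 255]")
  structure(list(pixels = pixels, resolution = resolution, metadata = metadata),
            class = "stain_image")
}

#' @export
print.stain_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stain_image> %d x %d px, 3 channels\n", d[1], d[2]))
  invisible(x)
}

#' Construct a stain segmentation (center spot + peripheral ring masks)
#'
#' @param center_mask,ring_mask logical matrices of identical dimensions;
#'   must be disjoint, each with at least 50 pixels.
#' @return An object of class `stain_segmentation`.
#' @export
stain_segmentation <- function(center_mask, ring_mask) {
  if (!is.logical(center_mask) || !is.logical(ring_mask) ||
      !identical(dim(center_mask), dim(ring_mask)))
    abort_validation("masks must be logical matrices of identical dimensions")
  if (any(center_mask & ring_mask))
    abort_validation("center and ring masks must be disjoint")
  if (sum(center_mask) < 50L || sum(ring_mask) < 50L)
    abort_validation("each mask must contain at least 50 pixels")
  structure(list(center_mask = center_mask, ring_mask = ring_mask),
            class = "stain_segmentation")
}

#' Specify a synthetic stain render
#'
#' Collects the sample, reagent and geometry parameters that determine a
#' synthetic blood stain. The default geometry places the center-spot
#' boundary at 0.35 of the stain radius, the same fixed fraction the
#' segmenter falls back to when no dark spot is present, so ground-truth
#' masks are well defined for 0\%-HbS stains too.
#'
#' @param hbs_percent \%HbS of the rendered sample, in \[0, 100\].
#' @param formulation reducing-agent formulation, see [stain_contrast()].
#' @param reagent_age_days reagent storage time (days).
#' @param storage `"wet"` or `"dry"` reagent storage.
#' @param temperature_c storage temperature (degrees C).
#' @param image_size_px edge length of the square raster.
#' @param stain_radius_px outer ring radius (pixels).
#' @param center_radius_px center-spot radius (pixels); must be strictly
#'   between 0 and `stain_radius_px`.
#' @param noise_sd per-pixel additive Gaussian noise SD (8-bit units),
#'   truncated by clipping to \[0, 255\].
#' @param shape_jitter relative amplitude of radial boundary irregularity
#'   (0 = perfect circles).
#' @param seed integer seed controlling noise and jitter.
#' @return An object of class `stain_render_spec`.
#' @export
stain_render_spec <- function(hbs_percent,
                              formulation = "MS",
                              reagent_age_days = 0,
                              storage = "dry",
                              temperature_c = 22,
                              image_size_px = 128L,
                              stain_radius_px = 44,
                              center_radius_px = 0.35 * stain_radius_px,
                              noise_sd = 2,
                              shape_jitter = 0,
                              seed = 1L) {
  if (!is_scalar_number(hbs_percent) || hbs_percent < 0 || hbs_percent > 100)
    abort_validation("hbs_percent must lie in [0, 100]")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    abort_validation("noise_sd must be non-negative")
  if (!is_scalar_number(shape_jitter) || shape_jitter < 0 || shape_jitter > 0.5)
    abort_validation("shape_jitter must lie in [0, 0.5]")
  if (!(center_radius_px > 0 && center_radius_px < stain_radius_px &&
        stain_radius_px < image_size_px / 2))
    stop_sicklestain("render_error",
      "geometry must satisfy 0 < center_radius_px < stain_radius_px < image_size_px/2")
  structure(list(
    hbs_percent = hbs_percent, formulation = formulation,
    reagent_age_days = reagent_age_days, storage = storage,
    temperature_c = temperature_c,
    image_size_px = as.integer(image_size_px),
    stain_radius_px = stain_radius_px, center_radius_px = center_radius_px,
    noise_sd = noise_sd, shape_jitter = shape_jitter, seed = as.integer(seed)
  ), class = "stain_render_spec")
}

# Seeded band-limited radial perturbation, scaled to max |f| = 1.
radial_jitter_fn <- function() {
  m <- 2:4
  a <- stats::rnorm(length(m)) / m
  b <- stats::rnorm(length(m)) / m
  function(theta) {
    f <- numeric(length(theta))
    for (i in seq_along(m)) f <- f + a[i] * cos(m[i] * theta) + b[i] * sin(m[i] * theta)
    amp <- max(abs(f), 1e-12)
    f / amp
  }
}

#' Render a synthetic blood stain with ground-truth segmentation
#'
#' Draws a stain as two concentric regions on a white background: a
#' peripheral pink ring (soluble hemoglobin wicked laterally through the
#' paper) and a center spot whose red color intensity, relative to the ring,
#' equals the contrast function [stain_contrast()] evaluated at the sample's
#' \%HbS — insoluble deoxy-HbS polymers trapped at the deposition point
#' darken the center. Reagents past their limit of stability (activity 0)
#' produce the same uniform pattern as a 0\%-HbS sample. Only the blue
#' channel carries the signal used by [s_index()]; red and green are
#' cosmetic. Per-pixel Gaussian noise is added per channel, clipped to
#' \[0, 255\] and rounded to 8 bits.
#'
#' @param spec a [stain_render_spec()].
#' @return An object of class `stain_render`: list with `image`
#'   (a [stain_image()]) and `truth` (the ground-truth
#'   [stain_segmentation()]).
#' @examples
#' r <- render_stain(stain_render_spec(40, "MS", noise_sd = 0))
#' s_index(r$image, r$truth)$s_index  # ~ stain_contrast(40, "MS")
#' @export
render_stain <- function(spec) {
  if (!inherits(spec, "stain_render_spec"))
    spec <- do.call(stain_render_spec, as.list(spec))
  act <- reagent_activity(spec$formulation, spec$storage,
                          spec$reagent_age_days, spec$temperature_c)
  g <- stain_contrast(spec$hbs_percent, spec$formulation)
  g_eff <- 1 + act$activity * (g - 1)

  n <- spec$image_size_px
  cxy <- (n - 1) / 2
  xs <- matrix(rep(0:(n - 1), each = n), n, n)   # column index
  ys <- matrix(rep(0:(n - 1), times = n), n, n)  # row index
  dx <- xs - cxy; dy <- ys - cxy
  dist <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  with_seed(spec$seed, {
    if (spec$shape_jitter > 0) {
      f_out <- radial_jitter_fn()
      f_in <- radial_jitter_fn()
      r_out <- spec$stain_radius_px * (1 + spec$shape_jitter * f_out(theta))
      r_in <- spec$center_radius_px * (1 + spec$shape_jitter * f_in(theta))
    } else {
      r_out <- spec$stain_radius_px
      r_in <- spec$center_radius_px
    }
    center <- dist <= r_in
    ring <- dist <= r_out & !center

    # Ring red intensity 100 (B = 155); center red intensity 100 * g_eff.
    base <- c(R = 235, G = 170, B = 155)
    px <- array(255, dim = c(n, n, 3))
    px[, , 1][ring] <- base["R"]
    px[, , 2][ring] <- base["G"]
    px[, , 3][ring] <- base["B"]
    px[, , 1][center] <- max(base["R"] - 30 * (g_eff - 1), 0)
    px[, , 2][center] <- max(base["G"] - 60 * (g_eff - 1), 0)
    px[, , 3][center] <- 255 - 100 * g_eff

    if (spec$noise_sd > 0)
      px <- px + array(stats::rnorm(length(px), 0, spec$noise_sd), dim = dim(px))
    px <- round(pmin(pmax(px, 0), 255))

    img <- stain_image(px, metadata = list(
      hbs_percent = spec$hbs_percent, formulation = spec$formulation,
      reagent_age_days = spec$reagent_age_days, storage = spec$storage,
      temperature_c = spec$temperature_c, activity = act$activity,
      expected_contrast = g_eff, seed = spec$seed
    ))
    structure(list(image = img, truth = stain_segmentation(center, ring)),
              class = "stain_render")
  })
}
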