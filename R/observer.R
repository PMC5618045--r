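#' Stochastic observer model for visual stain scoring
#'
#' Human raters classify a stain by its apparent center/ring contrast. The
#' model is an ordered-logit read of the S-index: a rater's latent percept is
#' the true S-index plus logistic noise of scale `1/slope`, cut at ordered
#' thresholds to produce a categorical call. As `slope` grows the rater
#' becomes deterministic (hard thresholding); at a cutpoint the probability
#' of calling the higher category is exactly 1/2.
#'
#' @param cutpoints strictly increasing S-index thresholds; one cutpoint for
#'   a binary negative/positive scheme, two for AA/AS/SS. Defaults are the
#'   midpoints separating the contrast levels of the MS formulation's
#'   0/10\% and 40/80\% HbS stains.
#' @param slope steepness of the call model (> 0, may be `Inf`).
#' @param seed integer seed.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(cutpoints = c(1.10, 2.06), slope = 40, seed = 1L) {
  if (length(cutpoints) < 1L || any(diff(cutpoints) <= 0))
    abort_validation("cutpoints must be strictly increasing")
  if (!(is.numeric(slope) && length(slope) == 1L && slope > 0))
    abort_validation("slope must be > 0")
  structure(list(cutpoints = as.numeric(cutpoints), slope = slope,
                 seed = as.integer(seed)),
            class = "observer_model")
}

#' Simulate categorical observer calls from S-index values
#'
#' @param s_indices numeric vector of S-index values, one per stain.
#' @param model an [observer_model()]; the number of cutpoints used is
#'   `length(class_scheme) - 1` (the first cutpoints are taken for a binary
#'   scheme).
#' @param class_scheme ordered category labels, `c("negative", "positive")`
#'   or `c("AA", "AS", "SS")`.
#' @param n_observers number of simulated raters.
#' @param n_replicates replicate readings per rater and stain.
#' @param true_hbs_percent optional vector of true \%HbS recorded alongside
#'   each call (recycled along `s_indices`).
#' @return A score table: data.frame with columns `observer_id`, `stain_id`,
#'   `replicate`, `call`, and `true_hbs_percent` (NA when not supplied).
#' @examples
#' m <- observer_model(cutpoints = 1.10, slope = Inf)
#' simulate_observer_calls(c(1.0, 1.5), m, c("negative", "positive"))
#' @export
simulate_observer_calls <- function(s_indices, model,
                                    class_scheme = c("negative", "positive"),
                                    n_observers = 3L, n_replicates = 1L,
                                    true_hbs_percent = NA_real_) {
  if (length(s_indices) == 0L)
    abort_validation("s_indices must be non-empty")
  k <- length(class_scheme) - 1L
  if (k < 1L || length(model$cutpoints) < k)
    abort_validation("class_scheme needs at least 2 labels and enough cutpoints")
  cuts <- model$cutpoints[seq_len(k)]
  truth <- rep_len(as.numeric(true_hbs_percent), length(s_indices))

  with_seed(model$seed, {
    grid <- expand.grid(
      replicate = seq_len(n_replicates),
      stain_idx = seq_along(s_indices),
      observer_id = seq_len(n_observers)
    )
    latent <- s_indices[grid$stain_idx]
    if (is.finite(model$slope))
      latent <- latent + stats::rlogis(nrow(grid)) / model$slope
    call <- class_scheme[findInterval(latent, cuts) + 1L]
    data.frame(
      observer_id = grid$observer_id,
      stain_id = grid$stain_idx,
      replicate = grid$replicate,
      call = factor(call, levels = class_scheme),
      true_hbs_percent = truth[grid$stain_idx],
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate replicate S-index measurements without rendering images
#'
#' Fast measurement-level counterpart of [render_stain()] followed by
#' [s_index()]: draws S-index values around the contrast model's expectation
#' with Gaussian measurement noise. Used for stability series and large
#' simulation studies where rendering every raster would be wasteful.
#'
#' @param hbs_percent \%HbS of the sample.
#' @param n number of replicate stains.
#' @inheritParams reagent_activity
#' @param noise_sd SD of S-index measurement noise (default 0.02, roughly
#'   the spread observed on rendered stains with per-pixel noise).
#' @param seed integer seed.
#' @return Numeric vector of `n` simulated S-index values.
#' @export
simulate_s_indices <- function(hbs_percent, n, formulation = "MS",
                               storage = "dry", age_days = 0,
                               temperature_c = 22, noise_sd = 0.02,
                               seed = NULL) {
  if (!is_scalar_number(n) || n < 1) abort_validation("n must be >= 1")
  act <- reagent_activity(formulation, storage, age_days, temperature_c)
  g <- 1 + act$activity * (stain_contrast(hbs_percent, formulation) - 1)
  with_seed(seed, g + stats::rnorm(n, 0, noise_sd))
}
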