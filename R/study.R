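#' Default configuration for a synthetic screening study
#'
#' @param n_per_class stains per \%HbS level.
#' @param hbs_levels true \%HbS levels sampled; the study's standard
#'   reconstitution targets are 0, 10, 20, 40 and 80\%.
#' @param formulation,storage,reagent_age_days reagent condition.
#' @param noise_sd per-pixel render noise SD (8-bit units).
#' @param shape_jitter boundary irregularity amplitude.
#' @param image_size_px,stain_radius_px render geometry.
#' @param class_scheme observer call labels.
#' @param n_observers,n_replicates rating design.
#' @param observer_slope steepness of the observer model.
#' @param seed master integer seed; all per-stain seeds derive from it.
#' @return A named list understood by [generate_study()].
#' @export
study_config <- function(n_per_class = 10L,
                         hbs_levels = c(0, 10, 20, 40, 80),
                         formulation = "MS", storage = "dry",
                         reagent_age_days = 0,
                         noise_sd = 2, shape_jitter = 0,
                         image_size_px = 128L, stain_radius_px = 44,
                         class_scheme = c("negative", "positive"),
                         n_observers = 3L, n_replicates = 1L,
                         observer_slope = 40, seed = 1L) {
  if (!is_scalar_number(n_per_class) || n_per_class < 1)
    abort_validation("n_per_class must be a positive integer")
  as.list(environment())
}

#' Generate a complete synthetic study fixture on disk
#'
#' Renders `n_per_class` stains at each \%HbS level, writes each as an 8-bit
#' RGB PNG, computes the noise-free-equivalent S-index of each render from
#' its ground-truth masks, simulates observer calls, and writes two CSVs:
#' `metadata.csv` (stain_id, filename, hbs_percent, formulation, storage,
#' age_days, expected_contrast, s_index_truth) and `scores.csv` (stain_id,
#' observer_id, replicate, call, true_hbs_percent). Byte-identical outputs
#' for identical configs and seeds.
#'
#' @param config a [study_config()] list.
#' @param dir output directory (created if missing).
#' @return Invisibly, a list with `metadata` and `scores` data frames and
#'   the file paths written.
#' @export
generate_study <- function(config = study_config(), dir = tempfile("study")) {
  cfg <- config
  if (cfg$n_per_class <= 0) abort_validation("n_per_class must be positive")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  levels_rep <- rep(cfg$hbs_levels, each = cfg$n_per_class)
  n <- length(levels_rep)
  stain_id <- seq_len(n)
  # independent render seed per stain, derived deterministically
  seeds <- cfg$seed * 10000L + stain_id

  s_true <- numeric(n)
  fname <- sprintf("stain_%03d.png", stain_id)
  for (i in stain_id) {
    r <- render_stain(stain_render_spec(
      hbs_percent = levels_rep[i], formulation = cfg$formulation,
      reagent_age_days = cfg$reagent_age_days, storage = cfg$storage,
      image_size_px = cfg$image_size_px, stain_radius_px = cfg$stain_radius_px,
      noise_sd = cfg$noise_sd, shape_jitter = cfg$shape_jitter,
      seed = seeds[i]
    ))
    write_stain_png(r$image, file.path(dir, fname[i]))
    s_true[i] <- s_index(r$image, r$truth)$s_index
  }

  metadata <- data.frame(
    stain_id = stain_id, filename = fname, hbs_percent = levels_rep,
    formulation = cfg$formulation, storage = cfg$storage,
    age_days = cfg$reagent_age_days,
    expected_contrast = stain_contrast(levels_rep, cfg$formulation),
    s_index_truth = s_true
  )
  model <- observer_model(slope = cfg$observer_slope, seed = cfg$seed + 1L)
  scores <- simulate_observer_calls(
    s_true, model, class_scheme = cfg$class_scheme,
    n_observers = cfg$n_observers, n_replicates = cfg$n_replicates,
    true_hbs_percent = levels_rep
  )
  meta_path <- file.path(dir, "metadata.csv")
  score_path <- file.path(dir, "scores.csv")
  utils::write.csv(metadata, meta_path, row.names = FALSE)
  utils::write.csv(scores, score_path, row.names = FALSE)
  invisible(list(metadata = metadata, scores = scores, dir = dir,
                 metadata_csv = meta_path, scores_csv = score_path))
}

#' Generate a reagent-aging stability series
#'
#' Simulates replicate S-index measurements at a grid of storage days for a
#' 0\%-HbS control group and an at-LOD group (10\% HbS for MS, 20\% for HS),
#' with reagent activity following the step-decay shelf-life model. The
#' default day grid brackets both HS step days (6 and 36) so the limit of
#' stability is identifiable from the series alone.
#'
#' @param formulation `"MS"` or `"HS"`.
#' @param storage `"wet"` or `"dry"`.
#' @param days storage-day grid (sorted, non-negative).
#' @param n_rep replicates per group per day.
#' @param lod_hbs_percent \%HbS of the at-LOD group; defaults to 10 for MS
#'   and 20 for HS.
#' @param noise_sd S-index measurement noise SD.
#' @param temperature_c storage temperature.
#' @param seed integer seed.
#' @return An object of class `stability_series`: data.frame with columns
#'   `day`, `group` (`"hbs0"` / `"lod"`), `replicate`, `s_index`, plus
#'   attributes `formulation`, `storage`, `lod_hbs_percent`.
#' @export
generate_stability_series <- function(formulation = "MS", storage = "wet",
                                      days = c(1, 2, 4, 6, 7, 10, 14, 21, 28,
                                               35, 36, 37, 42, 56, 84, 126, 168),
                                      n_rep = 10L,
                                      lod_hbs_percent = if (formulation == "HS") 20 else 10,
                                      noise_sd = 0.02, temperature_c = 22,
                                      seed = 1L) {
  if (is.unsorted(days, strictly = TRUE) || any(days < 0))
    abort_validation("days must be strictly increasing and non-negative")
  if (n_rep < 2L) abort_validation("need at least 2 replicates per group")
  rows <- vector("list", length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    s0 <- simulate_s_indices(0, n_rep, formulation, storage, d,
                             temperature_c, noise_sd, seed = seed * 1000L + 2L * i)
    s1 <- simulate_s_indices(lod_hbs_percent, n_rep, formulation, storage, d,
                             temperature_c, noise_sd, seed = seed * 1000L + 2L * i + 1L)
    rows[[i]] <- data.frame(
      day = d,
      group = rep(c("hbs0", "lod"), each = n_rep),
      replicate = rep(seq_len(n_rep), 2L),
      s_index = c(s0, s1)
    )
  }
  structure(do.call(rbind, rows), class = c("stability_series", "data.frame"),
            formulation = formulation, storage = storage,
            lod_hbs_percent = lod_hbs_percent)
}
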