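#' Limit of detection by ROC area under the curve
#'
#' The limit of detection (LOD) is the lowest \%HbS whose stains raters can
#' distinguish from 0\%-HbS stains. Given binary calls and the true \%HbS of
#' each stain, every candidate cutoff `c` defines a truth labeling
#' (positive when true \%HbS >= c); the candidate whose labeling best agrees
#' with the calls — greatest ROC AUC — is the LOD. For a single binary
#' rater the ROC has one operating point and
#' `AUC = (sensitivity + specificity) / 2`. Ties are broken toward the
#' lowest candidate (the LOD is the *lowest* detectable level). Candidates
#' under which the truth is single-class have undefined AUC and are
#' excluded.
#'
#' @param scores score table with binary `call`
#'   (`"negative"`/`"positive"`) and `true_hbs_percent`.
#' @param candidate_lods candidate \%HbS cutoffs (non-empty).
#' @return An object of class `lod_result`: list with `lod_percent`,
#'   `auc_by_candidate` (named numeric, `NA` for excluded candidates).
#' @export
lod_by_roc <- function(scores, candidate_lods = c(10, 20, 40, 80)) {
  if (length(candidate_lods) == 0L) abort_validation("candidate_lods must be non-empty")
  if (!all(c("call", "true_hbs_percent") %in% names(scores)))
    abort_validation("scores must have columns 'call' and 'true_hbs_percent'")
  calls <- as.character(scores$call)
  if (!all(calls %in% c("negative", "positive")))
    abort_validation("calls must be binary 'negative'/'positive'")
  pos_call <- calls == "positive"
  aucs <- vapply(candidate_lods, function(cc) {
    truth_pos <- scores$true_hbs_percent >= cc
    if (all(truth_pos) || !any(truth_pos)) return(NA_real_)
    sens <- mean(pos_call[truth_pos])
    spec <- mean(!pos_call[!truth_pos])
    (sens + spec) / 2
  }, numeric(1))
  names(aucs) <- as.character(candidate_lods)
  if (all(is.na(aucs)))
    abort_validation("AUC undefined for every candidate (single-class truth)")
  best <- max(aucs, na.rm = TRUE)
  lod <- min(candidate_lods[!is.na(aucs) & aucs == best])
  structure(list(lod_percent = lod, auc_by_candidate = aucs),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("LOD %g%% HbS (AUC %s)\n", x$lod_percent,
              paste(sprintf("%s: %.3f", names(x$auc_by_candidate),
                            x$auc_by_candidate), collapse = ", ")))
  invisible(x)
}

#' Total test readout time from per-minute scoring series
#'
#' As a stain dries, raters score it every minute; a class is readable once
#' every rater scores it correctly from some minute onward (a transient
#' correct spell followed by errors does not count). Total readout time is
#' the preparation/incubation time plus the largest per-class stable drying
#' time.
#'
#' @param timed_scores data.frame with columns `class`, `minute`,
#'   `observer_id`, `correct` (logical).
#' @param incubation_minutes preparation and incubation time before the
#'   mixture is deposited on paper (default 10).
#' @return An object of class `readout_time`: list with `per_class_minutes`
#'   (named, `NA` when a class never becomes uniformly correct),
#'   `total_minutes` (`NA` when any class has no stable readout) and
#'   `stable` (logical).
#' @export
readout_time <- function(timed_scores, incubation_minutes = 10) {
  need <- c("class", "minute", "observer_id", "correct")
  if (!all(need %in% names(timed_scores)))
    abort_validation("timed_scores must have columns class, minute, observer_id, correct")
  per_class <- vapply(split(seq_len(nrow(timed_scores)), timed_scores$class), function(i) {
    sub <- timed_scores[i, ]
    minutes <- sort(unique(sub$minute))
    ok_by_minute <- vapply(minutes, function(m) all(sub$correct[sub$minute == m]),
                           logical(1))
    # earliest minute from which every later reading is also correct
    wrong <- which(!ok_by_minute)
    if (length(wrong) == 0L) return(minutes[1])
    if (max(wrong) == length(minutes)) return(NA_real_)
    minutes[max(wrong) + 1L]
  }, numeric(1))
  stable <- !anyNA(per_class)
  structure(list(
    per_class_minutes = per_class,
    total_minutes = if (stable) incubation_minutes + max(per_class) else NA_real_,
    stable = stable
  ), class = "readout_time")
}

#' @export
print.readout_time <- function(x, ...) {
  if (x$stable) {
    cat(sprintf("readout time %g min (per-class drying: %s)\n", x$total_minutes,
                paste(sprintf("%s: %g", names(x$per_class_minutes),
                              x$per_class_minutes), collapse = ", ")))
  } else cat("no stable readout within scoring window\n")
  invisible(x)
}

#' Choose a buffer formulation from S-index dose-response curves
#'
#' Selection rule: prefer the formulation with the greatest S-index
#' difference between 0 and 20\% HbS (strongest low-\%HbS signal), breaking
#' ties by the most gradual S-index change over 20-40\% HbS (best dynamic
#' range for distinguishing trait from anemia).
#'
#' @param s_index_curves named list; each element a data.frame with columns
#'   `hbs_percent` and `s_index` covering at least 0, 20 and 40\% HbS.
#' @param tie_tolerance absolute tolerance within which first-criterion
#'   values count as tied.
#' @return Name of the chosen formulation.
#' @export
select_formulation <- function(s_index_curves, tie_tolerance = 1e-9) {
  if (length(s_index_curves) == 0L || is.null(names(s_index_curves)))
    abort_validation("s_index_curves must be a non-empty named list")
  at <- function(curve, x) {
    i <- which(curve$hbs_percent == x)
    if (length(i) != 1L)
      abort_validation(sprintf("curve missing required grid point %g%% HbS", x))
    curve$s_index[i]
  }
  crit <- t(vapply(s_index_curves, function(cv) {
    c(gain = at(cv, 20) - at(cv, 0), slope = abs(at(cv, 40) - at(cv, 20)))
  }, numeric(2)))
  best_gain <- max(crit[, "gain"])
  tied <- which(crit[, "gain"] >= best_gain - tie_tolerance)
  names(s_index_curves)[tied[which.min(crit[tied, "slope"])]]
}
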