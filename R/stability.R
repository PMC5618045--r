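#' Test whether a reagent still separates 0\%-HbS from at-LOD stains
#'
#' Welch's two-sample t-test (two-sided, unequal variances) for a difference
#' in mean S-index between stains made from 0\%-HbS samples and stains made
#' from samples at or above the limit of detection, using reagents of a
#' given age. A working reagent produces a significant difference; a dead
#' one does not. When both groups have zero variance and equal means the
#' p-value is 1 by convention and the result is flagged degenerate.
#'
#' @param zero_group,lod_group numeric vectors of replicate S-index values
#'   (each of length >= 2, finite).
#' @return An object of class `stability_test`: list with `p_value`,
#'   `statistic` (Welch t), `df`, `mean_difference` and `degenerate`.
#' @export
stability_test <- function(zero_group, lod_group) {
  if (length(zero_group) < 2L || length(lod_group) < 2L)
    abort_validation("each group needs at least 2 replicates")
  if (!all(is.finite(zero_group)) || !all(is.finite(lod_group)))
    abort_validation("S-index values must be finite")
  if (stats::var(zero_group) == 0 && stats::var(lod_group) == 0) {
    same <- mean(zero_group) == mean(lod_group)
    return(structure(list(
      p_value = if (same) 1 else 0,
      statistic = NA_real_, df = NA_real_,
      mean_difference = mean(lod_group) - mean(zero_group),
      degenerate = TRUE
    ), class = "stability_test"))
  }
  ht <- stats::t.test(lod_group, zero_group, var.equal = FALSE)
  structure(list(
    p_value = ht$p.value,
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    mean_difference = unname(ht$estimate[1] - ht$estimate[2]),
    degenerate = FALSE
  ), class = "stability_test")
}

#' @export
print.stability_test <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.2f, p = %.4g (mean S-index difference %.4f)\n",
              x$statistic, x$df, x$p_value, x$mean_difference))
  invisible(x)
}

#' Locate the limit of stability of a reagent series
#'
#' Applies [stability_test()] at every storage day of a series and finds the
#' limit of stability (LOS): the last day with a significant 0\%-vs-LOD
#' S-index difference strictly before the earliest non-significant day.
#' If the very first day is non-significant the LOS is 0; if every day is
#' significant, the LOS is the last observed day and is reported as
#' right-censored (the true limit is at least that long).
#'
#' @param series a [generate_stability_series()] result, or any data.frame
#'   with columns `day`, `group` (`"hbs0"`/`"lod"`) and `s_index`.
#' @param alpha significance level (default 0.05); no multiple-testing
#'   correction across days, matching the per-day stability criterion.
#' @return An object of class `stability_result`: list with `p_values`
#'   (data.frame day/p_value/stable), `limit_of_stability_days`, `censored`
#'   (TRUE when all days significant) and `alpha`.
#' @export
limit_of_stability <- function(series, alpha = 0.05) {
  if (!all(c("day", "group", "s_index") %in% names(series)))
    abort_validation("series must have columns day, group, s_index")
  days <- unique(series$day)
  if (is.unsorted(days, strictly = TRUE))
    abort_validation("series days must be sorted strictly increasing")
  p <- vapply(days, function(d) {
    sub <- series[series$day == d, ]
    stability_test(sub$s_index[sub$group == "hbs0"],
                   sub$s_index[sub$group == "lod"])$p_value
  }, numeric(1))
  stable <- p < alpha
  if (all(stable)) {
    los <- days[length(days)]
    censored <- TRUE
  } else {
    censored <- FALSE
    first_fail <- days[which(!stable)[1]]
    before <- days[stable & days < first_fail]
    los <- if (length(before) == 0L) 0 else max(before)
  }
  structure(list(
    p_values = data.frame(day = days, p_value = p, stable = stable),
    limit_of_stability_days = los, censored = censored, alpha = alpha
  ), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("limit of stability %s%g days (alpha = %g)\n",
              if (x$censored) ">= " else "", x$limit_of_stability_days, x$alpha))
  invisible(x)
}

#' Shelf-life ratio between two formulations or storage conditions
#'
#' @param los_a_days,los_b_days limits of stability in days (both > 0).
#' @param a_is_lower_bound set TRUE when `los_a_days` is right-censored
#'   (stable through the whole study), so the ratio is itself a lower bound
#'   and reported with a "~" qualifier.
#' @return An object of class `shelf_life_ratio`: list with `ratio`
#'   (unrounded), `rounded` (nearest integer) and `label` (e.g. `"~5x"`).
#' @examples
#' shelf_life_ratio(168, 7)$rounded   # 24
#' shelf_life_ratio(168, 35)$label    # "~5x"
#' @export
shelf_life_ratio <- function(los_a_days, los_b_days, a_is_lower_bound = TRUE) {
  if (!is_scalar_number(los_a_days) || !is_scalar_number(los_b_days) ||
      los_a_days <= 0 || los_b_days <= 0)
    abort_validation("both limits of stability must be > 0")
  r <- los_a_days / los_b_days
  structure(list(
    ratio = r, rounded = round(r),
    label = sprintf("%s%dx", if (a_is_lower_bound) "~" else "", round(r))
  ), class = "shelf_life_ratio")
}

#' @export
print.shelf_life_ratio <- function(x, ...) {
  cat(sprintf("shelf-life ratio %s (%.3g)\n", x$label, x$ratio))
  invisible(x)
}
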