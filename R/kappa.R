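#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for a fixed number `n` of categorical ratings
#' per subject. With `n_ij` the number of ratings of subject `i` in category
#' `j`, per-subject agreement is `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`,
#' the expected chance agreement is `P_e = sum_j p_j^2` with `p_j` the
#' overall category proportions, and
#' `kappa = (mean(P_i) - P_e) / (1 - P_e)`. Requires the same number of
#' ratings (>= 2) for every subject; no partial-rating extension is
#' provided. When every rating across all subjects falls in one category,
#' `P_e = 1` and kappa is undefined (`NaN`).
#'
#' @param x either a subjects x categories matrix of rating counts, or a
#'   score table (data.frame with columns `stain_id` and `call`; all ratings
#'   of a stain are pooled regardless of which rater made them).
#' @param ... unused.
#' @return Fleiss' kappa (scalar, <= 1).
#' @examples
#' # 2 subjects, 3 raters, category counts (2,1) and (2,1): kappa = -0.5
#' fleiss_kappa(matrix(c(2, 1, 2, 1), nrow = 2, byrow = TRUE))
#' @export
fleiss_kappa <- function(x, ...) UseMethod("fleiss_kappa")

#' @export
fleiss_kappa.matrix <- function(x, ...) {
  if (any(x < 0) || any(x != round(x)))
    abort_validation("rating counts must be non-negative integers")
  n_per_subject <- rowSums(x)
  n <- n_per_subject[1]
  if (n < 2 || any(n_per_subject != n))
    abort_validation("every subject must be rated the same number of times (>= 2)")
  p_i <- (rowSums(x^2) - n) / (n * (n - 1))
  p_j <- colSums(x) / sum(x)
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  (p_bar - p_e) / (1 - p_e)
}

#' @export
fleiss_kappa.data.frame <- function(x, ...) {
  if (!all(c("stain_id", "call") %in% names(x)))
    abort_validation("score table must have columns 'stain_id' and 'call'")
  counts <- table(x$stain_id, factor(x$call))
  fleiss_kappa(matrix(as.integer(counts), nrow = nrow(counts)))
}

#' Per-observer intra-rater kappa
#'
#' Self-consistency of each rater: within one observer, the replicate
#' readings of each stain are treated as the "ratings" of the Fleiss
#' formulation, giving one kappa per observer.
#'
#' @param scores score table with columns `observer_id`, `stain_id`,
#'   `replicate`, `call`; every observer must have >= 2 replicates per
#'   stain.
#' @return Named numeric vector of kappas, one per observer.
#' @export
intra_observer_kappas <- function(scores) {
  need <- c("observer_id", "stain_id", "replicate", "call")
  if (!all(need %in% names(scores)))
    abort_validation("score table must have columns observer_id, stain_id, replicate, call")
  lv <- sort(unique(as.character(scores$call)))
  ks <- tapply(seq_len(nrow(scores)), scores$observer_id, function(i) {
    sub <- scores[i, ]
    counts <- table(sub$stain_id, factor(as.character(sub$call), levels = lv))
    fleiss_kappa(matrix(as.integer(counts), nrow = nrow(counts)))
  })
  out <- as.numeric(ks)
  names(out) <- names(ks)
  out
}

#' Summarize per-observer agreement values
#'
#' @param kappas numeric vector of at least two per-observer kappas.
#' @return An object of class `agreement_summary`: list with unrounded
#'   `mean` and `sd` (population convention, divisor `n`), their 2-decimal
#'   reporting values `mean_rounded`/`sd_rounded`, and a `label` like
#'   `"0.93 +/- 0.04"`.
#' @examples
#' agreement_summary(c(0.88, 0.93, 0.97))
#' @export
agreement_summary <- function(kappas) {
  if (length(kappas) < 2L || anyNA(kappas))
    abort_validation("need at least two finite agreement values")
  m <- mean(kappas)
  s <- sqrt(mean((kappas - m)^2))
  structure(list(
    mean = m, sd = s,
    mean_rounded = round(m, 2), sd_rounded = round(s, 2),
    label = sprintf("%.2f +/- %.2f", round(m, 2), round(s, 2))
  ), class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("kappa", x$label, "\n")
  invisible(x)
}
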