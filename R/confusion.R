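#' Genotype class scheme on \%HbS
#'
#' Truth labeling by characteristic HbS fraction: normal (`AA`) below the
#' trait threshold, sickle cell trait (`AS`) between the trait threshold and
#' the anemia threshold, sickle cell anemia (`SS`) above it. The standard
#' scheme uses AA = 0\%, AS = 10-40\%, SS > 40\%. Two binary screening tasks
#' derive from it: "AA vs rest" (positive when \%HbS >= 10) and "SS vs rest"
#' (positive when \%HbS >= 80, characteristic of SCA).
#'
#' @param as_min lowest \%HbS counted as trait (default 10).
#' @param ss_min lowest \%HbS counted as anemia in the three-class truth
#'   labeling (default > 40, i.e. anything above `as_max`).
#' @param as_max highest \%HbS counted as trait (default 40).
#' @param ss_binary_min positive threshold of the "SS vs rest" binary task
#'   (default 80).
#' @return An object of class `genotype_scheme`.
#' @export
genotype_scheme <- function(as_min = 10, as_max = 40, ss_binary_min = 80) {
  if (!(as_min < as_max && as_max < ss_binary_min))
    abort_validation("scheme boundaries must be ordered: as_min < as_max < ss_binary_min")
  structure(list(classes = c("AA", "AS", "SS"),
                 as_min = as_min, as_max = as_max,
                 ss_binary_min = ss_binary_min),
            class = "genotype_scheme")
}

#' True class labels from \%HbS under a genotype scheme
#'
#' @param hbs_percent numeric vector of true \%HbS.
#' @param scheme a [genotype_scheme()].
#' @param task `"three_class"` for AA/AS/SS, `"aa_vs_rest"` or
#'   `"ss_vs_rest"` for the binary screening tasks
#'   (negative/positive labels).
#' @return Factor of truth labels.
#' @export
truth_labels <- function(hbs_percent, scheme = genotype_scheme(),
                         task = c("three_class", "aa_vs_rest", "ss_vs_rest")) {
  task <- match.arg(task)
  if (anyNA(hbs_percent))
    abort_validation("true %HbS missing for some records")
  switch(task,
    three_class = factor(
      ifelse(hbs_percent < scheme$as_min, "AA",
             ifelse(hbs_percent <= scheme$as_max, "AS", "SS")),
      levels = scheme$classes),
    aa_vs_rest = factor(ifelse(hbs_percent >= scheme$as_min, "positive", "negative"),
                        levels = c("negative", "positive")),
    ss_vs_rest = factor(ifelse(hbs_percent >= scheme$ss_binary_min, "positive", "negative"),
                        levels = c("negative", "positive"))
  )
}

#' Aggregate confusion matrix from a score table
#'
#' Pools all observers and replicates: each record contributes one count at
#' (true class, called class). True classes derive from `true_hbs_percent`
#' under the scheme; calls must already use the same label set.
#'
#' @param scores score table with columns `call` and `true_hbs_percent`.
#' @param scheme a [genotype_scheme()].
#' @param task see [truth_labels()]; default matches the call labels
#'   (three-class when calls are AA/AS/SS, "aa_vs_rest" when
#'   negative/positive).
#' @return An object of class `confusion_matrix`: integer K x K matrix,
#'   rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(scores, scheme = genotype_scheme(), task = NULL) {
  if (!all(c("call", "true_hbs_percent") %in% names(scores)))
    abort_validation("scores must have columns 'call' and 'true_hbs_percent'")
  calls <- as.character(scores$call)
  if (is.null(task))
    task <- if (all(calls %in% scheme$classes)) "three_class" else "aa_vs_rest"
  truth <- truth_labels(scores$true_hbs_percent, scheme, task)
  labs <- levels(truth)
  if (!all(calls %in% labs))
    abort_validation(sprintf("calls outside label set {%s}: %s",
                             paste(labs, collapse = ", "),
                             paste(unique(setdiff(calls, labs)), collapse = ", ")))
  tab <- table(truth = truth, call = factor(calls, levels = labs))
  m <- matrix(as.integer(tab), nrow = length(labs),
              dimnames = list(true = labs, predicted = labs))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Build a 2x2 confusion matrix directly from counts
#'
#' @param tp,fp,tn,fn non-negative integer counts (rows = true class,
#'   positive class second).
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) abort_validation("counts must be >= 0")
  if (tp + fp + tn + fn == 0) abort_validation("total count must be > 0")
  m <- matrix(as.integer(c(tn, fp, fn, tp)), nrow = 2, byrow = TRUE,
              dimnames = list(true = c("negative", "positive"),
                              predicted = c("negative", "positive")))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Diagnostic performance metrics from a confusion matrix
#'
#' Collapses a K x K confusion matrix to 2 x 2 against a positive class set
#' and computes sensitivity = TP/(TP+FN), specificity = TN/(FP+TN),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN) and accuracy = (TP+TN)/total. Metrics
#' with a zero denominator are reported as `NA` and listed in `undefined`
#' rather than coerced to 0.
#'
#' @param cm a [confusion_matrix()].
#' @param positive_classes labels counted as positive (non-empty proper
#'   subset of the matrix labels); default `"positive"`.
#' @return An object of class `diagnostic_metrics`: list with `tp`, `fp`,
#'   `tn`, `fn`, the five metrics (proportions in \[0, 1\]), and
#'   `undefined` (character vector of metrics with 0/0 denominators).
#' @export
binary_metrics <- function(cm, positive_classes = "positive") {
  stopifnot(inherits(cm, "confusion_matrix"))
  labs <- rownames(cm)
  if (length(positive_classes) == 0L || !all(positive_classes %in% labs) ||
      length(positive_classes) >= length(labs))
    abort_validation("positive_classes must be a non-empty proper subset of the labels")
  pos <- labs %in% positive_classes
  tp <- sum(cm[pos, pos]); fn <- sum(cm[pos, !pos])
  fp <- sum(cm[!pos, pos]); tn <- sum(cm[!pos, !pos])
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, fp + tn),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = ratio(tp + tn, tp + fp + tn + fn)
  )
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv", "accuracy")],
    is.na, logical(1))))
  structure(out, class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, digits = 1, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf(paste0("%.", digits, "f%%"), 100 * v)
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sensitivity %s  specificity %s  PPV %s  NPV %s  accuracy %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$ppv),
              pct(x$npv), pct(x$accuracy)))
  invisible(x)
}

#' Find 2x2 confusion matrices consistent with reported metrics
#'
#' Published evaluations often report the five performance percentages and
#' the total number of scores but not the underlying confusion cells. This
#' searches all non-negative integer 2x2 matrices with the given total whose
#' metrics round to the reported values.
#'
#' @param total total number of scores.
#' @param sensitivity,specificity,ppv,npv,accuracy reported percentages
#'   (0-100); any may be `NA` to leave unconstrained.
#' @param digits rounding precision of the reported percentages.
#' @return data.frame of matching `(tp, fp, tn, fn)` rows (possibly empty).
#' @export
search_confusion_counts <- function(total, sensitivity = NA, specificity = NA,
                                    ppv = NA, npv = NA, accuracy = NA,
                                    digits = 1) {
  matches_rounded <- function(value, reported) {
    is.na(reported) | (!is.na(value) & round(100 * value, digits) == reported)
  }
  hits <- list()
  for (p in 1:(total - 1)) {
    n_neg <- total - p
    for (tp in 0:p) {
      fn <- p - tp
      if (!matches_rounded(tp / p, sensitivity)) next
      for (fp in 0:n_neg) {
        tn <- n_neg - fp
        ok <- matches_rounded(tn / n_neg, specificity) &&
          matches_rounded(if (tp + fp > 0) tp / (tp + fp) else NA, ppv) &&
          matches_rounded(if (tn + fn > 0) tn / (tn + fn) else NA, npv) &&
          matches_rounded((tp + tn) / total, accuracy)
        if (ok) hits[[length(hits) + 1L]] <- c(tp = tp, fp = fp, tn = tn, fn = fn)
      }
    }
  }
  as.data.frame(do.call(rbind, hits))
}
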