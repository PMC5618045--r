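make_scores <- function(truth_hbs, calls) {
  data.frame(observer_id = 1L, stain_id = seq_along(calls), replicate = 1L,
             call = calls, true_hbs_percent = truth_hbs)
}

test_that("all-correct calls give a diagonal confusion matrix", {
  hbs <- rep(c(0, 20, 80), times = c(4, 5, 6))
  calls <- c(rep("AA", 4), rep("AS", 5), rep("SS", 6))
  cm <- confusion_matrix(make_scores(hbs, calls))
  expect_equal(sum(cm), 15)
  expect_equal(sum(diag(cm)), 15)
})

test_that("pooling observers reproduces the samples-times-users total", {
  # 185 stains x 3 observers = 555 pooled scores
  hbs <- rep(c(0, 20, 80), length.out = 185)
  scores <- do.call(rbind, lapply(1:3, function(o) {
    s <- make_scores(hbs, as.character(truth_labels(hbs)))
    s$observer_id <- o
    s
  }))
  cm <- confusion_matrix(scores)
  expect_equal(sum(cm), 555)
})

test_that("confusion tally matches a naive counting loop on random tables", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    hbs <- sample(c(0, 10, 20, 40, 80), n, replace = TRUE)
    calls <- sample(c("AA", "AS", "SS"), n, replace = TRUE)
    cm <- confusion_matrix(make_scores(hbs, calls))
    truth <- as.character(truth_labels(hbs))
    expect_true(all(unclass(cm) == naive_confusion_tally(truth, calls, c("AA", "AS", "SS"))))
  }
})

test_that("calls outside the label set are rejected", {
  expect_error(confusion_matrix(make_scores(c(0, 80), c("AA", "XX"))),
               class = "validation_error")
})

test_that("perfect 2x2 classification yields all-1 metrics", {
  m <- binary_metrics(confusion_from_counts(tp = 5, fp = 0, tn = 5, fn = 0))
  for (f in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    expect_equal(m[[f]], 1)
  expect_length(m$undefined, 0)
})

test_that("the published screening metrics follow from their counts", {
  m <- binary_metrics(confusion_from_counts(tp = 412, fp = 0, tn = 111, fn = 32))
  expect_equal(round(100 * m$sensitivity, 1), 92.8)
  expect_equal(round(100 * m$specificity, 1), 100)
  expect_equal(round(100 * m$ppv, 1), 100)
  expect_equal(round(100 * m$npv, 1), 77.6)
  expect_equal(round(100 * m$accuracy, 1), 94.2)
})

test_that("metrics equal the direct formulas on random 2x2 tables", {
  set.seed(17)
  for (i in 1:25) {
    k <- sample(0:50, 4, replace = TRUE)
    if (sum(k) == 0) next
    m <- binary_metrics(confusion_from_counts(k[1], k[2], k[3], k[4]))
    if (k[1] + k[4] > 0) expect_equal(m$sensitivity, k[1] / (k[1] + k[4]), tolerance = 1e-12)
    if (k[2] + k[3] > 0) expect_equal(m$specificity, k[3] / (k[2] + k[3]), tolerance = 1e-12)
    expect_equal(m$accuracy, (k[1] + k[3]) / sum(k), tolerance = 1e-12)
  }
})

test_that("zero-denominator metrics are undefined, not zero", {
  m <- binary_metrics(confusion_from_counts(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_setequal(m$undefined, c("sensitivity", "ppv"))
})

test_that("integer search recovers matrices consistent with reported metrics", {
  hits <- search_confusion_counts(555, sensitivity = 92.8, specificity = 100,
                                  ppv = 100, npv = 77.6, accuracy = 94.2)
  expect_gt(nrow(hits), 0)
  expect_true(any(hits$tp == 412 & hits$fn == 32 & hits$tn == 111 & hits$fp == 0))
})
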