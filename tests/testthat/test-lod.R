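binary_scores <- function(hbs, calls) {
  data.frame(observer_id = 1L, stain_id = seq_along(calls), replicate = 1L,
             call = calls, true_hbs_percent = hbs)
}

test_that("perfectly separable calls place the LOD at the separating level", {
  hbs <- rep(c(0, 10, 20, 40, 80), each = 10)
  calls <- ifelse(hbs >= 10, "positive", "negative")
  res <- lod_by_roc(binary_scores(hbs, calls), c(10, 20, 40, 80))
  expect_equal(res$lod_percent, 10)
  expect_equal(unname(res$auc_by_candidate["10"]), 1)
  expect_true(all(res$auc_by_candidate[c("20", "40", "80")] < 1))
})

test_that("the printed count pattern yields the expected single-point AUC", {
  # 888 positives of which 820 called positive; 222 negatives, 220 correct
  hbs <- rep(c(10, 0), times = c(888, 222))
  calls <- c(rep("positive", 820), rep("negative", 68),
             rep("negative", 220), rep("positive", 2))
  res <- lod_by_roc(binary_scores(hbs, calls), 10)
  expect_equal(unname(res$auc_by_candidate["10"]),
               (820 / 888 + 220 / 222) / 2, tolerance = 1e-12)
})

test_that("an uninformative rater scores AUC 0.5 everywhere", {
  hbs <- rep(c(0, 10, 40), each = 10)
  res <- lod_by_roc(binary_scores(hbs, rep("positive", 30)), c(10, 40))
  expect_true(all(res$auc_by_candidate == 0.5))
  # ties break toward the lowest candidate: LOD is the lowest percentage
  expect_equal(res$lod_percent, 10)
})

test_that("single-class candidates are excluded, empty input rejected", {
  hbs <- rep(c(10, 40), each = 5)
  calls <- rep(c("negative", "positive"), each = 5)
  res <- lod_by_roc(binary_scores(hbs, calls), c(5, 20))
  expect_true(is.na(res$auc_by_candidate["5"]))  # all truths positive at 5
  expect_false(is.na(res$auc_by_candidate["20"]))
  expect_error(lod_by_roc(binary_scores(hbs, calls), numeric(0)),
               class = "validation_error")
  expect_error(lod_by_roc(binary_scores(hbs, calls), c(5)),
               class = "validation_error")
})

test_that("AUC matches the naive tally on random binary score sets", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    hbs <- sample(c(0, 10, 40), n, replace = TRUE)
    calls <- sample(c("negative", "positive"), n, replace = TRUE)
    truth_pos <- hbs >= 10
    if (all(truth_pos) || !any(truth_pos)) next
    res <- lod_by_roc(binary_scores(hbs, calls), 10)
    expect_equal(unname(res$auc_by_candidate["10"]),
                 naive_single_point_auc(truth_pos, calls == "positive"),
                 tolerance = 1e-12)
  }
})

make_timed <- function(stable_after, n_min = 25) {
  # every observer wrong strictly before `stable_after`, correct from it on
  do.call(rbind, lapply(names(stable_after), function(cl) {
    expand.grid(class = cl, minute = 1:n_min, observer_id = 1:3,
                KEEP.OUT.ATTRS = FALSE) |>
      transform(correct = minute >= stable_after[[cl]])
  }))
}

test_that("readout time adds incubation to the slowest stable class", {
  timed <- make_timed(list(AA = 7, AS = 11, SS = 1))
  res <- readout_time(timed, incubation_minutes = 10)
  expect_equal(unname(res$per_class_minutes[c("AA", "AS", "SS")]), c(7, 11, 1))
  expect_equal(res$total_minutes, 21)
})

test_that("classes correct from the start add no drying time", {
  timed <- make_timed(list(AA = 0, SS = 0), n_min = 5)
  timed$minute <- timed$minute - 1  # scored from minute 0
  res <- readout_time(timed, incubation_minutes = 10)
  expect_equal(res$total_minutes, 10)
})

test_that("transient correct spells are ignored in favor of the stable time", {
  timed <- make_timed(list(AA = 4), n_min = 12)
  # observer 2 relapses at minutes 6-7, so stability only starts at 8
  timed$correct[timed$observer_id == 2 & timed$minute %in% 6:7] <- FALSE
  res <- readout_time(timed, incubation_minutes = 10)
  # brute-force scan oracle over the series
  oracle <- NA
  for (t0 in sort(unique(timed$minute))) {
    later <- timed[timed$minute >= t0, ]
    if (all(later$correct)) { oracle <- t0; break }
  }
  expect_equal(unname(res$per_class_minutes[["AA"]]), oracle)
  expect_equal(res$total_minutes, 10 + 8)
})

test_that("a class never uniformly correct is reported unstable", {
  timed <- make_timed(list(AA = 3), n_min = 10)
  timed$correct[timed$minute == 10 & timed$observer_id == 1] <- FALSE
  res <- readout_time(timed)
  expect_false(res$stable)
  expect_true(is.na(res$total_minutes))
})

test_that("formulation selection follows the lexicographic criterion", {
  curve <- function(s0, s20, s40)
    data.frame(hbs_percent = c(0, 20, 40), s_index = c(s0, s20, s40))
  # dominating candidate wins outright
  expect_equal(select_formulation(list(a = curve(1, 1.6, 1.9),
                                       b = curve(1, 1.3, 2.0))), "a")
  # tied on the 0-20 gain: the more gradual 20-40 slope wins
  expect_equal(select_formulation(list(a = curve(1, 1.5, 2.2),
                                       b = curve(1, 1.5, 1.8))), "b")
  expect_error(select_formulation(list(a = data.frame(hbs_percent = c(0, 20),
                                                      s_index = c(1, 1.5)))),
               class = "validation_error")
})

test_that("15% MS wins the selection among the generator's MS variants", {
  grid <- c(0, 20, 40)
  curves <- lapply(c(MS10 = "MS10", MS15 = "MS15", MS20 = "MS20"), function(f)
    data.frame(hbs_percent = grid, s_index = stain_contrast(grid, f)))
  expect_equal(select_formulation(curves), "MS15")
})
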