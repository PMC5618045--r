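test_that("identical groups are not significantly different", {
  res <- stability_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  res2 <- stability_test(c(1.00, 1.01, 0.99, 1.02), c(1.01, 0.99, 1.00, 1.02))
  expect_gt(res2$p_value, 0.5)
})

test_that("well-separated groups are detected, agreeing with a permutation test", {
  set.seed(19)
  x <- rnorm(20, 1.0, 0.01)
  y <- rnorm(20, 2.0, 0.01)
  res <- stability_test(x, y)
  expect_lt(res$p_value, 1e-6)
  # permutation oracle: with complete separation the smallest achievable
  # p is 1/(B+1); both tests must call the difference significant
  expect_lt(permutation_p_value(x, y), 0.001)

  # moderate case: Welch and permutation p-values agree within MC error
  x2 <- rnorm(15, 1.00, 0.05)
  y2 <- rnorm(15, 1.03, 0.05)
  p_w <- stability_test(x2, y2)$p_value
  p_perm <- permutation_p_value(x2, y2, n_perm = 4000)
  expect_lt(abs(p_w - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.01)
})

test_that("the Welch statistic matches a 3-vs-3 hand calculation", {
  x <- c(1.0, 1.1, 1.2)   # mean 1.1, var 0.01
  y <- c(2.0, 2.2, 2.1)   # mean 2.1, var 0.01
  res <- stability_test(x, y)
  se <- sqrt(0.01 / 3 + 0.01 / 3)
  t_hand <- (2.1 - 1.1) / se                     # 12.2474...
  df_hand <- (0.01 / 3 + 0.01 / 3)^2 /
    ((0.01 / 3)^2 / 2 + (0.01 / 3)^2 / 2)        # 4
  expect_equal(abs(res$statistic), t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-t_hand, df_hand), tolerance = 1e-10)
  expect_equal(res$mean_difference, 1, tolerance = 1e-12)
})

test_that("group size and finiteness are validated", {
  expect_error(stability_test(1, c(1, 2)), class = "validation_error")
  expect_error(stability_test(c(1, NA, 2), c(1, 2)), class = "validation_error")
})

test_that("limit of stability recovers the generator's step days", {
  wet <- generate_stability_series("HS", "wet", n_rep = 10, seed = 21)
  res_wet <- limit_of_stability(wet)
  expect_equal(res_wet$limit_of_stability_days, 6)
  expect_false(res_wet$censored)

  dry <- generate_stability_series("HS", "dry", n_rep = 10, seed = 22)
  res_dry <- limit_of_stability(dry)
  expect_equal(res_dry$limit_of_stability_days, 36)

  ms <- generate_stability_series("MS", "wet", n_rep = 10, seed = 23)
  res_ms <- limit_of_stability(ms)
  expect_true(res_ms$censored)
  expect_equal(res_ms$limit_of_stability_days, 168)
})

test_that("LOS boundary rules: immediate failure and post-failure recoveries", {
  mk <- function(day, p_sig) {
    # two-point groups engineered to be clearly different or identical
    do.call(rbind, lapply(seq_along(day), function(i) {
      lod_vals <- if (p_sig[i]) c(2.00, 2.01, 1.99, 2.02) else c(1.00, 1.01, 0.99, 1.02)
      data.frame(day = day[i], group = rep(c("hbs0", "lod"), each = 4),
                 s_index = c(c(1.00, 1.01, 0.99, 1.02), lod_vals))
    }))
  }
  expect_equal(limit_of_stability(mk(c(1, 5), c(FALSE, TRUE)))$limit_of_stability_days, 0)
  # a significant day after the first failure does not extend the LOS
  res <- limit_of_stability(mk(c(1, 5, 9, 13), c(TRUE, TRUE, FALSE, TRUE)))
  expect_equal(res$limit_of_stability_days, 5)
  expect_error(limit_of_stability(mk(c(5, 1), c(TRUE, TRUE))),
               class = "validation_error")
})

test_that("LOS recovery holds across seeded replicate series", {
  # Days on the live side of the step differ by ~10 within-group SDs, so the
  # LOS is never underestimated. Days past the step are true nulls, so each
  # is spuriously significant at rate alpha; a series overestimates the LOS
  # only when the first post-step day false-positives (prob alpha = 0.05).
  los <- vapply(1:20, function(seed) {
    ser <- generate_stability_series("HS", "wet", days = c(2, 4, 6, 7, 9),
                                     n_rep = 8, seed = seed)
    limit_of_stability(ser)$limit_of_stability_days
  }, numeric(1))
  expect_true(all(los >= 6))
  expect_gte(mean(los == 6), 0.8)
})

test_that("shelf-life ratios compare limits of stability", {
  expect_equal(shelf_life_ratio(24 * 7, 7)$rounded, 24)
  r <- shelf_life_ratio(24 * 7, 5 * 7)
  expect_equal(r$ratio, 4.8)
  expect_equal(r$rounded, 5)
  expect_equal(r$label, "~5x")
  expect_equal(shelf_life_ratio(42, 42)$ratio, 1)
  expect_error(shelf_life_ratio(42, 0), class = "validation_error")
})
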