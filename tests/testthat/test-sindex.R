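make_masks <- function(n = 64) {
  center <- matrix(FALSE, n, n); center[20:35, 20:35] <- TRUE
  ring <- matrix(FALSE, n, n); ring[2:15, ] <- TRUE
  list(center = center, ring = ring)
}

test_that("uniform images give S-index 1 under any partition", {
  m <- make_masks()
  img <- stain_image(array(140, dim = c(64, 64, 3)))
  expect_equal(s_index(img, stain_segmentation(m$center, m$ring))$s_index, 1)
})

test_that("piecewise-constant blue channel forces the analytic ratio", {
  m <- make_masks()
  px <- array(200, dim = c(64, 64, 3))
  px[, , 3][m$center] <- 55    # red 200
  px[, , 3][m$ring] <- 155     # red 100
  res <- s_index(stain_image(px), stain_segmentation(m$center, m$ring))
  expect_equal(res$s_index, 2)
  expect_equal(res$center_mean_red, 200)
  expect_equal(res$ring_mean_red, 100)
})

test_that("vectorized S-index equals the naive per-pixel loop", {
  m <- make_masks(48)
  set.seed(31)
  for (i in 1:25) {
    px <- array(sample(0:254, 48 * 48 * 3, replace = TRUE), dim = c(48, 48, 3))
    seg <- stain_segmentation(m$center[1:48, 1:48], m$ring[1:48, 1:48])
    expect_equal(s_index(stain_image(px), seg)$s_index,
                 naive_s_index(px, seg$center_mask, seg$ring_mask),
                 tolerance = 1e-12)
  }
})

test_that("only the blue channel enters the S-index", {
  m <- make_masks()
  seg <- stain_segmentation(m$center, m$ring)
  set.seed(7)
  px <- array(sample(0:254, 64 * 64 * 3, replace = TRUE), dim = c(64, 64, 3))
  base <- s_index(stain_image(px), seg)$s_index
  px2 <- px
  px2[, , 1] <- sample(0:255, 64 * 64, replace = TRUE)
  px2[, , 2] <- sample(0:255, 64 * 64, replace = TRUE)
  expect_identical(s_index(stain_image(px2), seg)$s_index, base)
})

test_that("darkening the center strictly increases the S-index", {
  m <- make_masks()
  seg <- stain_segmentation(m$center, m$ring)
  px <- array(150, dim = c(64, 64, 3))
  s1 <- s_index(stain_image(px), seg)$s_index
  px[, , 3][m$center] <- 120  # lower B = darker red center
  s2 <- s_index(stain_image(px), seg)$s_index
  expect_gt(s2, s1)
})

test_that("a pure-white ring is reported as degenerate", {
  m <- make_masks()
  px <- array(100, dim = c(64, 64, 3))
  px[, , 3][m$ring] <- 255
  expect_error(s_index(stain_image(px), stain_segmentation(m$center, m$ring)),
               class = "degenerate_input")
})

test_that("batch analysis preserves order and flags failures", {
  d <- withr::local_tempdir()
  levels <- c(0, 10, 20, 40, 80)
  for (i in seq_along(levels)) {
    r <- quick_render(levels[i], noise_sd = 2, seed = i)
    write_stain_png(r$image, file.path(d, sprintf("s%02d.png", i)))
  }
  png::writePNG(array(1, dim = c(64, 64, 3)), file.path(d, "s99_blank.png"))
  out <- analyze_batch(d)
  expect_equal(nrow(out), 6)
  expect_equal(out$stain_id, sort(out$stain_id))
  expect_equal(sum(out$flag == "ok"), 5)
  expect_equal(out$flag[out$stain_id == "s99_blank.png"], "no_stain_found")
  expect_true(is.na(out$s_index[out$flag != "ok"]))
  # S-index increases with %HbS across the batch
  expect_true(all(diff(out$s_index[order(out$stain_id)][1:5]) > 0))
  # CSV side effect
  csv <- withr::local_tempfile(fileext = ".csv")
  analyze_batch(d, output_csv = csv)
  expect_true(file.exists(csv))
  expect_error(analyze_batch(withr::local_tempdir()), class = "validation_error")
})
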