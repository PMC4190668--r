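test_that("histogram features: single-bin, symmetric and oracle cases", {
  h <- histogram_features(matrix(128L, 10, 10))
  expect_equal(h[9], 1)           # bin 8 (0-based) holds intensity 128
  expect_equal(sum(h), 1)

  chk <- matrix(c(0L, 255L), 8, 8)
  h2 <- histogram_features(chk)
  expect_equal(h2[1], 0.5)
  expect_equal(h2[16], 0.5)
  expect_equal(sum(h2[2:15]), 0)

  set.seed(99)
  g <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_equal(histogram_features(g), oracle_hist16(g))

  expect_error(histogram_features(integer(0)), "empty")
})

test_that("texture features: constant patch has zero contrast and ripples", {
  tx <- texture_features(matrix(200L, 24, 24))
  expect_length(tx, 13)
  expect_true(all(is.finite(tx)))
  expect_equal(unname(tx["contrast"]), 0)
  expect_equal(unname(tx[sprintf("ripple_%d", 1:7)]), rep(0, 7),
               ignore_attr = TRUE)
})

test_that("coarseness orders stripe periods correctly", {
  stripes <- function(period, n = 64) {
    x <- matrix(rep(0:(n - 1), each = n), n, n)
    matrix(as.integer(255 * ((x %/% (period / 2)) %% 2)), n, n)
  }
  c8 <- texture_features(stripes(8))["coarseness"]
  c32 <- texture_features(stripes(32))["coarseness"]
  expect_gt(c32, c8)
})

test_that("a pure sinusoid concentrates ripple power in its band", {
  n <- 64
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  g <- matrix(as.integer(round(128 + 100 * sin(2 * pi * x / 8))), n, n)
  tx <- texture_features(g)
  ripples <- tx[sprintf("ripple_%d", 1:7)]
  # frequency 1/8 = 0.125 cycles/px falls in the documented band layout
  edges <- 0.5 * 2^(-(7:0))
  band <- max(min(findInterval(0.125, edges, rightmost.closed = TRUE), 7), 1)
  expect_gte(ripples[band] / sum(ripples), 0.9)
})

test_that("extract_features populates all 39 entries", {
  fig <- figure_image(matrix(180L, 60, 90))
  full <- segment("s", bbox(0, 0, 90, 60), kind = "GRAPHIC")
  fv <- extract_features(fig, full)
  expect_length(fv, 39)
  expect_identical(names(fv), feature_names())
  expect_equal(unname(fv[c("rel_x", "rel_y", "rel_w", "rel_h")]),
               c(0.5, 0.5, 1, 1))
  expect_equal(unname(fv[c("abs_w", "abs_h")]), c(90, 60))
  expect_error(extract_features(fig, segment("o", bbox(0, 0, 100, 60))),
               "bounds")
})

test_that("feature vector matches a straight-line reference on a fixture", {
  set.seed(12)
  W <- 120; H <- 80
  px <- array(sample(0:255, H * W * 3, replace = TRUE), dim = c(H, W, 3))
  fig <- figure_image(px, "fx")
  b <- c(10, 20, 60, 52)
  seg <- segment("s", bbox(b[1], b[2], b[3], b[4]), kind = "TEXT",
                 text = "LOX")
  fv <- extract_features(fig, seg)
  # independent reference: per-pixel loops over the crop
  crop <- px[(b[2] + 1):b[4], (b[1] + 1):b[3], , drop = FALSE]
  g <- round(0.299 * crop[, , 1] + 0.587 * crop[, , 2] + 0.114 * crop[, , 3])
  expect_equal(unname(fv["rel_x"]), mean(c(b[1], b[3])) / W)
  expect_equal(unname(fv["rel_y"]), mean(c(b[2], b[4])) / H)
  expect_equal(unname(fv["rel_w"]), (b[3] - b[1]) / W)
  expect_equal(unname(fv["abs_h"]), b[4] - b[2])
  expect_equal(unname(fv[sprintf("hist_%02d", 1:16)]), oracle_hist16(g))
  expect_equal(unname(fv["color_r"]), sum(crop[, , 1]) / length(crop[, , 1]))
  expect_equal(unname(fv["color_g"]), sum(crop[, , 2]) / length(crop[, , 2]))
  expect_equal(unname(fv["n_chars"]), 3)
  # deterministic: repeated extraction is bit-identical
  expect_identical(fv, extract_features(fig, seg))
})

test_that("translation changes only the two position features", {
  set.seed(7)
  patch <- array(sample(0:255, 30 * 40 * 3, replace = TRUE), dim = c(30, 40, 3))
  canvas <- array(255L, dim = c(200, 300, 3))
  put <- function(canvas, patch, x, y) {
    canvas[(y + 1):(y + 30), (x + 1):(x + 40), ] <- patch
    canvas
  }
  f1 <- figure_image(put(canvas, patch, 20, 30))
  f2 <- figure_image(put(canvas, patch, 180, 120))
  v1 <- extract_features(f1, segment("a", bbox(20, 30, 60, 60)))
  v2 <- extract_features(f2, segment("a", bbox(180, 120, 220, 150)))
  moved <- names(v1)[v1 != v2]
  expect_setequal(moved, c("rel_x", "rel_y"))
  expect_identical(v1[setdiff(names(v1), c("rel_x", "rel_y"))],
                   v2[setdiff(names(v2), c("rel_x", "rel_y"))])
})

test_that("small segments are measured on a zero-padded 16x16 canvas", {
  tiny <- texture_features(matrix(100L, 5, 5))
  expect_length(tiny, 13)
  expect_true(all(is.finite(tiny)))
})

test_that("feature CSV export/import round-trips", {
  set.seed(3)
  fa <- generate_figure(generator_config(seed = 3, p_gel_figure = 1), 1)
  fm <- feature_matrix(fa$figure, fa$annotation$segments)
  is_gel <- vapply(fa$annotation$segments, function(s) isTRUE(s$is_gel), TRUE)
  tf <- withr::local_tempfile(fileext = ".csv")
  export_features(fm, is_gel, tf)
  back <- import_features(tf)
  expect_equal(back$features, fm)
  expect_equal(back$is_gel, is_gel)
})
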