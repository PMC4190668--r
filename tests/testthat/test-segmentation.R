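blank_cfg <- segmentation_config(min_segment_area = 4, ocr_enabled = FALSE)

test_that("detect_segments finds nothing on a blank figure", {
  fig <- figure_image(matrix(255L, 60, 80))
  expect_identical(detect_segments(fig, blank_cfg), list())
  expect_identical(detect_rectangles(fig), list())
})

test_that("detect_segments recovers separated dark blocks exactly", {
  m <- matrix(255L, 120, 160)
  truth <- list(c(10, 10, 50, 30), c(70, 15, 120, 40), c(20, 60, 80, 100))
  for (b in truth) m[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- 30L
  segs <- detect_segments(figure_image(m), blank_cfg)
  expect_length(segs, 3)
  # reading order: top-to-bottom then left-to-right by bbox origin
  ord <- order(vapply(truth, `[[`, 0, 2), vapply(truth, `[[`, 0, 1))
  for (i in seq_along(segs))
    expect_true(all(abs(segs[[i]]$bbox - truth[[ord[i]]]) <= 2))
})

test_that("diagonally touching blocks stay separate under 4-connectivity", {
  m <- matrix(255L, 40, 40)
  m[6:15, 6:15] <- 0L
  m[16:25, 16:25] <- 0L  # shares only the corner pixel diagonal
  segs <- detect_segments(figure_image(m), blank_cfg)
  expect_length(segs, 2)
  # agreement with a pure-R flood-fill oracle
  lab <- oracle_flood_label(m < 128)
  expect_equal(max(lab), 2)
})

test_that("component labeling agrees with the flood-fill oracle on random masks", {
  set.seed(42)
  for (rep in 1:20) {
    mask <- matrix(runif(30 * 30) < 0.35, 30, 30)
    got <- gelminer:::.label_components(mask)
    want <- oracle_flood_label(mask)
    expect_equal(max(got), max(want))
    # identical partition (labels may differ only by renaming)
    expect_equal(got > 0, want > 0)
    if (max(got) > 0)
      expect_true(all(tapply(want[want > 0], got[got > 0],
                             function(v) length(unique(v))) == 1))
  }
})

test_that("rectangle detector finds a uniform light-gray rectangle", {
  m <- matrix(255L, 150, 200)
  m[41:100, 31:150] <- 200L  # bbox (30, 40, 150, 100)
  rects <- detect_rectangles(figure_image(m))
  expect_length(rects, 1)
  expect_true(all(abs(rects[[1]]$bbox - c(30, 40, 150, 100)) <= 2))
  expect_equal(rects[[1]]$kind, "GRAPHIC")
  expect_equal(rects[[1]]$source, "RECTANGLE_DETECTOR")
})

test_that("nested frames are both reported", {
  m <- matrix(255L, 120, 160)
  frame <- function(m, b, v) {
    m[(b[2] + 1):b[4], (b[1] + 1):(b[1] + 2)] <- v
    m[(b[2] + 1):b[4], (b[3] - 1):b[3]] <- v
    m[(b[2] + 1):(b[2] + 2), (b[1] + 1):b[3]] <- v
    m[(b[4] - 1):b[4], (b[1] + 1):b[3]] <- v
    m
  }
  m <- frame(m, c(20, 20, 140, 90), 200L)
  m <- frame(m, c(45, 40, 110, 70), 200L)
  rects <- detect_rectangles(figure_image(m))
  expect_length(rects, 2)
  got <- lapply(rects, `[[`, "bbox")
  for (want in list(c(20, 20, 140, 90), c(45, 40, 110, 70)))
    expect_true(any(vapply(got, function(g) all(abs(g - want) <= 2), TRUE)))
})

test_that("noiseless synthetic rectangles are recovered exactly (set equivalence)", {
  set.seed(77)
  for (rep in 1:5) {
    m <- matrix(255L, 220, 320)
    truth <- list()
    for (k in 1:3) {
      for (try in 1:50) {
        w <- sample(60:110, 1); h <- sample(30:60, 1)
        x0 <- sample(5:(320 - w - 5), 1); y0 <- sample(5:(220 - h - 5), 1)
        b <- c(x0, y0, x0 + w, y0 + h)
        clear <- all(vapply(truth, function(t)
          oracle_gap_distance(t, b) > 12, TRUE))
        if (clear) {
          truth[[length(truth) + 1]] <- b
          m[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)] <- sample(185:215, 1)
          break
        }
      }
    }
    rects <- detect_rectangles(figure_image(m))
    expect_length(rects, length(truth))
    matched <- vapply(truth, function(t)
      any(vapply(rects, function(r) bbox_iou(r$bbox, t) >= 0.9, TRUE)), TRUE)
    expect_true(all(matched))
  }
})

test_that("segment detection is invariant under padded translation", {
  m <- matrix(255L, 80, 80)
  m[21:40, 11:50] <- 20L
  m[51:70, 31:60] <- 60L
  big <- matrix(255L, 140, 150)
  dx <- 37; dy <- 23
  big[(1 + dy):(80 + dy), (1 + dx):(80 + dx)] <- m
  s1 <- detect_segments(figure_image(m), blank_cfg)
  s2 <- detect_segments(figure_image(big), blank_cfg)
  expect_equal(length(s1), length(s2))
  for (i in seq_along(s1))
    expect_equal(s2[[i]]$bbox, s1[[i]]$bbox + c(dx, dy, dx, dy))
})

test_that("segments stay in bounds with positive area", {
  set.seed(5)
  fa <- generate_figure(generator_config(seed = 5, p_gel_figure = 1), 3)
  segs <- segment_figure(fa$figure, blank_cfg)
  for (s in segs) {
    expect_true(s$bbox[[1]] >= 0 && s$bbox[[2]] >= 0)
    expect_true(s$bbox[[3]] <= fa$figure$width)
    expect_true(s$bbox[[4]] <= fa$figure$height)
    expect_gt(bbox_area(s$bbox), 0)
  }
})

test_that("duplicate suppression keeps the rectangle-detector box", {
  m <- matrix(255L, 100, 150)
  m[21:60, 21:120] <- 120L  # dark enough for both detectors
  segs <- segment_figure(figure_image(m),
                         segmentation_config(min_segment_area = 50,
                                             ocr_enabled = FALSE))
  expect_length(segs, 1)
  expect_equal(segs[[1]]$source, "RECTANGLE_DETECTOR")
})

test_that("run_ocr honors the adapter contract", {
  fig <- figure_image(matrix(255L, 40, 60))
  seg <- segment("t1", bbox(5, 5, 55, 25), kind = "TEXT")
  mock <- ocr_mock(list("5,5,55,25" = "LOX"))
  expect_equal(run_ocr(fig, seg, mock), "LOX")
  expect_equal(run_ocr(fig, seg, ocr_mock()), "")     # empty region/unknown
  expect_equal(run_ocr(fig, segment("t2", bbox(0, 0, 10, 10), kind = "TEXT"),
                       ocr_none()), "")
  expect_error(run_ocr(fig, segment("g", bbox(0, 0, 5, 5)), mock),
               "TEXT")
  # engine failure is a warning + empty string, never fatal
  boom <- function(crop) stop("engine crashed")
  expect_warning(out <- run_ocr(fig, seg, boom), "OCR engine failed")
  expect_equal(out, "")
})

test_that("template OCR reads bundled-font labels (>= 80% of 50)", {
  set.seed(404)
  pool <- generator_config()$label_pool
  oc <- ocr_template()
  labels <- sample(pool, 50, replace = TRUE)
  hits <- vapply(labels, function(s) {
    r <- oc(render_text(s, scale = sample(2:3, 1)))
    identical(r$text, s)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("OCR-driven TEXT/GRAPHIC calls separate labels from gel patches", {
  cfg <- segmentation_config(min_segment_area = 20)
  # a label and a gel strip on one canvas; the glyphs L, E, F, T are
  # 4-connected, so the baseline detector yields one segment per glyph
  # (glyphs with diagonal joints would fragment -- a known limitation of
  # the stand-in segmenter)
  m <- matrix(255L, 120, 260)
  tm <- render_text("LEFT", scale = 2)
  m[11:(10 + nrow(tm)), 11:(10 + ncol(tm))] <- tm
  set.seed(8)
  gs <- generate_gel_segment(w = 120, h = 40)
  m[61:100, 101:220] <- gs$pixels
  segs <- segment_figure(figure_image(m), cfg, ocr = ocr_template())
  kinds <- vapply(segs, function(s) s$kind, "")
  texts <- vapply(segs, function(s) s$text, "")
  expect_true("TEXT" %in% kinds)
  # reading order reassembles the label from the per-glyph segments
  expect_equal(paste(texts[kinds == "TEXT"], collapse = ""), "LEFT")
  # the gel region (low contrast) must come out GRAPHIC
  gel_like <- vapply(segs, function(s) bbox_iou(s$bbox, c(100, 60, 220, 100)) > 0.5, TRUE)
  expect_true(any(gel_like))
  expect_true(all(kinds[gel_like] == "GRAPHIC"))
})
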