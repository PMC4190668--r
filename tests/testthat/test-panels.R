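test_that("segment_distance matches the named cases and the boundary oracle", {
  expect_equal(segment_distance(bbox(0, 0, 10, 10), bbox(5, 5, 20, 20)), 0)
  expect_equal(segment_distance(bbox(0, 0, 10, 10), bbox(20, 0, 30, 10)), 10)
  expect_equal(segment_distance(bbox(0, 0, 10, 10), bbox(13, 14, 20, 20)), 5)
  # touching boxes are at distance 0
  expect_equal(segment_distance(bbox(0, 0, 10, 10), bbox(10, 0, 20, 10)), 0)
  set.seed(61)
  for (i in 1:50) {
    a <- c(x0 <- sample(0:40, 1), y0 <- sample(0:40, 1),
           x0 + sample(3:15, 1), y0 + sample(3:15, 1))
    b <- c(x1 <- sample(0:40, 1), y1 <- sample(0:40, 1),
           x1 + sample(3:15, 1), y1 + sample(3:15, 1))
    expect_equal(segment_distance(a, b), oracle_box_distance(a, b))
  }
})

test_that("has_text_between matches the pixel-enumeration oracle", {
  a <- bbox(0, 0, 30, 30)
  b <- bbox(60, 0, 90, 30)
  txt <- function(bb) segment("t", bb, kind = "TEXT", text = "x")
  expect_false(has_text_between(a, b, list()))
  expect_true(has_text_between(a, b, list(txt(bbox(38, 5, 52, 15)))))
  expect_false(has_text_between(a, b, list(txt(bbox(30, 40, 60, 50)))))  # below hull
  expect_false(has_text_between(a, b, list(txt(bbox(5, 5, 20, 15)))))    # inside a
  set.seed(62)
  for (i in 1:150) {
    aa <- c(x <- sample(0:60, 1), y <- sample(0:60, 1),
            x + sample(5:25, 1), y + sample(5:25, 1))
    bb <- c(x <- sample(0:60, 1), y <- sample(0:60, 1),
            x + sample(5:25, 1), y + sample(5:25, 1))
    tt <- c(x <- sample(0:80, 1), y <- sample(0:80, 1),
            x + sample(3:30, 1), y + sample(3:12, 1))
    got <- has_text_between(aa, bb, list(txt(bbox(tt[1], tt[2], tt[3], tt[4]))))
    expect_identical(got, oracle_text_between_pixels(aa, bb, tt))
    expect_identical(got, oracle_text_between_area(aa, bb, tt))
  }
})

group_fixture <- function(boxes, scores, texts = list()) {
  layout <- list(boxes = boxes, scores = scores, texts = texts)
  segs <- layout_segments(layout)
  group_gel_segments(segs, make_score_classifier(), layout_features(layout))
}

test_that("grouping follows the seed-and-expand rules", {
  # a lone high-precision seed
  expect_equal(group_fixture(list(c(0, 0, 40, 20)), 0.65), list("g01"))
  # HP + HR-only neighbor 40 px apart, nothing between -> merged
  expect_equal(
    group_fixture(list(c(0, 0, 40, 20), c(80, 0, 120, 20)), c(0.65, 0.20)),
    list(c("g01", "g02")))
  # same pair with a text segment in the corridor -> HR singleton dropped
  expect_equal(
    group_fixture(list(c(0, 0, 40, 20), c(80, 0, 120, 20)), c(0.65, 0.20),
                  list(c(50, 5, 70, 15))),
    list("g01"))
  # two HR-only segments close together but no HP seed -> nothing
  expect_equal(
    group_fixture(list(c(0, 0, 40, 20), c(50, 0, 90, 20)), c(0.20, 0.20)),
    list())
  # empty input
  expect_equal(group_gel_segments(list(), make_score_classifier(),
                                  matrix(0, 0, 1)), list())
})

test_that("label attribution applies the 30 / 150 px rules", {
  region <- bbox(100, 100, 300, 200)
  lab <- function(id, bb) segment(id, bb, kind = "TEXT", text = id)
  texts <- list(
    lab("near", bbox(120, 64, 220, 80)),     # nearest 20, farthest ~103
    lab("toofar", bbox(120, 40, 220, 60)),   # nearest 40 -> rejected
    lab("longbar", bbox(100, 70, 600, 80)))  # nearest 20 but corner > 150
  got <- attribute_labels(region, texts)
  expect_equal(vapply(got, function(t) t$segment_id, ""), "near")
  # widening far_px admits the long bar
  got2 <- attribute_labels(region, texts, far_px = 400)
  expect_setequal(vapply(got2, function(t) t$segment_id, ""),
                  c("near", "longbar"))
})

test_that("detect_panels assembles the 2x4 grid with its 6 labels", {
  cfg <- generator_config(seed = 7, p_gel_figure = 1,
                          panel_rows = 2, panel_cols = 4)
  fa <- generate_figure(cfg, 2)
  ann <- fa$annotation
  expect_length(ann$panels, 1)
  expect_length(ann$panels[[1]]$members, 8)
  expect_length(ann$panels[[1]]$labels, 6)
  # a perfect scorer (1 for true gel segments, 0 otherwise)
  scores <- vapply(ann$segments, function(s) as.numeric(isTRUE(s$is_gel)), 0)
  fm <- matrix(scores, ncol = 1,
               dimnames = list(vapply(ann$segments,
                                      function(s) s$segment_id, "")))
  panels <- detect_panels(fa$figure, ann$segments, make_score_classifier(), fm)
  expect_length(panels, 1)
  expect_setequal(panels[[1]]$members, ann$panels[[1]]$members)
  expect_setequal(panels[[1]]$labels, ann$panels[[1]]$labels)
})

test_that("well-separated groups become separate panels", {
  boxes <- list(c(0, 0, 40, 20), c(0, 30, 40, 50), c(300, 0, 340, 20))
  got <- group_fixture(boxes, c(0.65, 0.65, 0.65))
  expect_equal(got, list(c("g01", "g02"), "g03"))
})

test_that("no high-precision positives means no panels", {
  fa <- generate_figure(generator_config(seed = 13, p_gel_figure = 1), 4)
  ann <- fa$annotation
  fm <- matrix(0.2, nrow = length(ann$segments), ncol = 1,
               dimnames = list(vapply(ann$segments,
                                      function(s) s$segment_id, "")))
  expect_length(detect_panels(fa$figure, ann$segments,
                              make_score_classifier(), fm), 0)
})

test_that("grouping matches the brute-force oracle on random layouts", {
  set.seed(63)
  clf <- make_score_classifier()
  for (i in 1:150) {
    layout <- random_layout()
    got <- group_gel_segments(layout_segments(layout), clf,
                              layout_features(layout))
    want <- oracle_grouping(layout)
    expect_equal(got, want)
    # structural invariants
    all_members <- unlist(got)
    expect_equal(anyDuplicated(all_members), 0)
    hp_ids <- sprintf("g%02d", which(layout$scores >= 0.6))
    hr_ids <- sprintf("g%02d", which(layout$scores >= 0.15))
    for (grp in got) {
      expect_true(all(grp %in% hr_ids))
      expect_true(any(grp %in% hp_ids))
    }
  }
})

test_that("larger adjacency never shrinks the largest group (text-free)", {
  set.seed(64)
  clf <- make_score_classifier()
  for (i in 1:40) {
    layout <- random_layout()
    layout$texts <- list()
    layout$scores[1] <- 0.8  # guarantee a seed
    segs <- layout_segments(layout)
    fm <- layout_features(layout)
    sizes <- vapply(c(20, 50, 80), function(adj) {
      g <- group_gel_segments(segs, clf, fm, adjacency_px = adj)
      if (length(g)) max(lengths(g)) else 0L
    }, 0L)
    expect_true(all(diff(sizes) >= 0))
  }
})
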