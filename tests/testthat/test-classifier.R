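separable_data <- function() {
  set.seed(21)
  x <- rbind(matrix(rnorm(10 * 3, mean = 0), ncol = 3),
             matrix(rnorm(10 * 3, mean = 6), ncol = 3))
  list(x = x, y = rep(c(FALSE, TRUE), each = 10))
}

test_that("training defaults to 75 trees and records metadata", {
  d <- separable_data()
  clf <- gel_train(d$x, d$y, seed = 4)
  expect_length(clf$forest, 75)
  expect_equal(clf$n_trees, 75)
  expect_equal(clf$training_meta$n_samples, 20)
  expect_equal(clf$training_meta$class_balance, 0.5)
  expect_equal(clf$training_meta$seed, 4)
})

test_that("linearly separable clusters are fit perfectly", {
  d <- separable_data()
  clf <- gel_train(d$x, d$y, seed = 4)
  expect_equal(gel_classify(clf, d$x, "balanced"), d$y)
})

test_that("training is deterministic given the seed", {
  set.seed(30)
  x <- matrix(rnorm(200 * 4), ncol = 4)  # noisy, so seeds matter
  y <- x[, 1] + rnorm(200) > 0
  probe <- matrix(rnorm(200), ncol = 4)
  s1 <- gel_score(gel_train(x, y, seed = 9), probe)
  s2 <- gel_score(gel_train(x, y, seed = 9), probe)
  expect_identical(s1, s2)
  s3 <- gel_score(gel_train(x, y, seed = 10), probe)
  expect_false(identical(s1, s3))
})

test_that("single-class input is an error", {
  expect_error(gel_train(matrix(rnorm(30), ncol = 3), rep(TRUE, 10)),
               "both")
})

test_that("score is the tree-vote fraction", {
  # hand-built forest of three leaf trees voting (1, 0, 1)
  leaf <- function(p) list(feat = -1L, thr = 0, left = -1L, right = -1L,
                           pred = as.integer(p))
  clf <- structure(list(forest = list(leaf(1), leaf(0), leaf(1)),
                        n_trees = 3L, thresholds = gel_thresholds(),
                        feature_names = NULL,
                        training_meta = list()),
                   class = "gel_classifier")
  expect_equal(gel_score(clf, matrix(0, 1, 1)), 2 / 3)
  # unanimity
  clf$forest <- list(leaf(1), leaf(1), leaf(1))
  expect_equal(gel_score(clf, matrix(0, 1, 1)), 1)
  # stateless: identical on repeated calls
  expect_identical(gel_score(clf, matrix(0, 1, 1)),
                   gel_score(clf, matrix(0, 1, 1)))
})

test_that("operating points apply the 0.15 / 0.30 / 0.60 thresholds", {
  clf <- make_score_classifier()
  at <- function(score, op) gel_classify(clf, matrix(score, 1, 1), op)
  expect_true(at(0.65, "high_recall"))
  expect_true(at(0.65, "balanced"))
  expect_true(at(0.65, "high_precision"))
  expect_true(at(0.20, "high_recall"))
  expect_false(at(0.20, "balanced"))
  expect_false(at(0.20, "high_precision"))
  expect_false(at(0, "high_recall"))
  expect_false(at(0, "balanced"))
  expect_false(at(0, "high_precision"))
})

test_that("evaluation computes the confusion-derived metrics", {
  clf <- make_score_classifier()
  # at the balanced threshold 0.3: TP=3, FP=1, FN=1, TN=2
  x <- matrix(c(0.8, 0.8, 0.8, 0.8, 0.1, 0.1, 0.1, 0.9), ncol = 1)
  y <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  x[8] <- 0.05
  x[4] <- 0.9
  ev <- gel_evaluate(clf, x, y, "balanced")
  expect_equal(unname(ev$confusion), c(3, 1, 1, 3))
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$f_score, 0.75)

  # a perfect scorer
  xp <- matrix(c(1, 1, 0, 0), ncol = 1)
  yp <- c(TRUE, TRUE, FALSE, FALSE)
  evp <- gel_evaluate(clf, xp, yp, "balanced")
  expect_equal(c(evp$precision, evp$recall, evp$f_score, evp$roc_auc),
               c(1, 1, 1, 1))

  # constant scores carry no information
  evc <- gel_evaluate(clf, matrix(0.5, 4, 1), yp, "balanced")
  expect_equal(evc$roc_auc, 0.5)

  expect_error(gel_evaluate(clf, matrix(0, 0, 1), logical(0)), "empty")
})

test_that("threshold nesting holds for a trained forest", {
  set.seed(31)
  x <- matrix(rnorm(400 * 6), ncol = 6)
  y <- x[, 1] + 0.7 * x[, 2] + rnorm(400) > 0.5
  clf <- gel_train(x, y, seed = 2)
  probe <- matrix(rnorm(200 * 6), ncol = 6)
  hp <- which(gel_classify(clf, probe, "high_precision"))
  bal <- which(gel_classify(clf, probe, "balanced"))
  hr <- which(gel_classify(clf, probe, "high_recall"))
  expect_true(all(hp %in% bal))
  expect_true(all(bal %in% hr))
})

test_that("models persist as versioned JSON and schema mismatches error", {
  d <- separable_data()
  x <- d$x
  colnames(x) <- c("f1", "f2", "f3")
  clf <- gel_train(x, d$y, seed = 4)
  tf <- withr::local_tempfile(fileext = ".json")
  save_gel_classifier(clf, tf)
  back <- load_gel_classifier(tf)
  expect_identical(gel_score(back, x), gel_score(clf, x))
  expect_equal(back$thresholds, clf$thresholds)
  expect_equal(back$training_meta$seed, 4)

  bad <- x[, 1:2]
  expect_error(gel_score(back, bad), "schema")
  wrong <- x
  colnames(wrong) <- c("a", "b", "c")
  expect_error(gel_score(back, wrong), "schema")

  # format version is checked
  j <- jsonlite::fromJSON(tf, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  j$format <- "something-else"
  tf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, tf2, auto_unbox = TRUE, digits = NA)
  expect_error(load_gel_classifier(tf2), "format")
})
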