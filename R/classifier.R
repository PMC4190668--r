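#' Default decision thresholds for the gel classifier
#'
#' The same trained forest is read at three vote-fraction thresholds:
#' 0.15 (high recall, used to expand panel groups), 0.30 (balanced) and
#' 0.60 (high precision, used to seed panel groups). Lower thresholds give
#' higher recall at the cost of precision, and vice versa.
#'
#' @return named numeric vector `c(high_recall = 0.15, balanced = 0.30,
#'   high_precision = 0.60)`.
#' @export
gel_thresholds <- function() {
  c(high_recall = 0.15, balanced = 0.30, high_precision = 0.60)
}

#' Train the random-forest gel-segment classifier
#'
#' Fits a forest of CART trees (Gini impurity, bootstrap resampling,
#' `mtry = floor(sqrt(p))` random features per node) on labeled feature
#' vectors. Class imbalance (gel segments are a small minority, about 3%
#' of segments in real figure corpora) is handled purely by reading the
#' vote-fraction score at different thresholds, not by resampling.
#' Training is bit-reproducible for a fixed `seed`.
#'
#' @param features numeric matrix, one row per segment (columns =
#'   [feature_names()] or any fixed schema).
#' @param is_gel logical (or 0/1) labels; both classes must be present.
#' @param n_trees number of trees (default 75).
#' @param seed integer RNG seed.
#' @param mtry features tried per split; default `floor(sqrt(ncol))`.
#' @param min_node minimum samples per leaf.
#' @param thresholds named thresholds, see [gel_thresholds()].
#' @return an object of class `gel_classifier`.
#' @export
gel_train <- function(features, is_gel, n_trees = 75, seed = 1,
                      mtry = NULL, min_node = 1,
                      thresholds = gel_thresholds()) {
  features <- as.matrix(features)
  y <- as.integer(as.logical(is_gel))
  if (anyNA(y) || anyNA(features)) stop("labels and features must be complete")
  if (length(y) != nrow(features)) stop("labels must align with feature rows")
  if (length(unique(y)) < 2)
    stop("training data must contain both gel and non-gel examples")
  stopifnot(thresholds[["high_recall"]] > 0,
            thresholds[["high_recall"]] < thresholds[["balanced"]],
            thresholds[["balanced"]] < thresholds[["high_precision"]],
            thresholds[["high_precision"]] < 1)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(features))))
  set.seed(as.integer(seed))
  forest <- .rf_build(features, y, as.integer(n_trees), as.integer(mtry),
                      as.integer(min_node))
  structure(list(
    forest = forest,
    n_trees = as.integer(n_trees),
    thresholds = thresholds,
    feature_names = colnames(features),
    training_meta = list(n_samples = nrow(features),
                         class_balance = mean(y),
                         seed = as.integer(seed),
                         mtry = as.integer(mtry),
                         min_node = as.integer(min_node))),
    class = "gel_classifier")
}

#' @export
print.gel_classifier <- function(x, ...) {
  cat(sprintf("<gel_classifier: %d trees, trained on %d segments (%.1f%% gel), seed %d>\n",
              x$n_trees, x$training_meta$n_samples,
              100 * x$training_meta$class_balance, x$training_meta$seed))
  invisible(x)
}

as_feature_matrix <- function(clf, fv) {
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1,
                                     dimnames = list(NULL, names(fv)))
  fv <- as.matrix(fv)
  if (!is.null(clf$feature_names) && !is.null(colnames(fv))) {
    if (!identical(colnames(fv), clf$feature_names)) {
      if (!all(clf$feature_names %in% colnames(fv)))
        stop("feature schema mismatch: missing ",
             paste(setdiff(clf$feature_names, colnames(fv)), collapse = ", "))
      fv <- fv[, clf$feature_names, drop = FALSE]
    }
  }
  if (!is.null(clf$feature_names) && ncol(fv) != length(clf$feature_names))
    stop("feature schema mismatch: expected ", length(clf$feature_names),
         " features, got ", ncol(fv))
  fv
}

#' Score segments: fraction of trees voting gel
#'
#' @param clf a [gel_train()]ed classifier.
#' @param fv a feature vector or matrix (one row per segment).
#' @return numeric scores in `[0, 1]`.
#' @export
gel_score <- function(clf, fv) {
  stopifnot(inherits(clf, "gel_classifier"))
  as.numeric(.rf_votes(clf$forest, as_feature_matrix(clf, fv)))
}

#' Classify at an operating point
#'
#' Positive iff `gel_score(clf, fv) >= clf$thresholds[[operating_point]]`,
#' so the positive set at a higher threshold is always a subset of the
#' positive set at a lower one.
#'
#' @inheritParams gel_score
#' @param operating_point `"high_recall"`, `"balanced"` or
#'   `"high_precision"`.
#' @return logical vector.
#' @export
gel_classify <- function(clf, fv,
                         operating_point = c("balanced", "high_recall",
                                             "high_precision")) {
  operating_point <- match.arg(operating_point)
  gel_score(clf, fv) >= clf$thresholds[[operating_point]]
}

# rank-based (Mann-Whitney) ROC AUC; ties get mean ranks
roc_auc <- function(scores, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier on a labeled set
#'
#' Precision, recall and F-score at the chosen operating point, plus the
#' threshold-sweep ROC AUC of the raw scores (0.5 for an uninformative
#' scorer, 1.0 for a perfect one).
#'
#' @inheritParams gel_classify
#' @param is_gel logical labels for the rows of `fv`.
#' @return an object of class `gel_eval` with fields `precision`, `recall`,
#'   `f_score`, `roc_auc`, `confusion` (tp/fp/fn/tn) and `operating_point`.
#' @export
gel_evaluate <- function(clf, fv, is_gel,
                         operating_point = c("balanced", "high_recall",
                                             "high_precision")) {
  operating_point <- match.arg(operating_point)
  y <- as.logical(is_gel)
  if (!length(y)) stop("empty test set")
  pred <- gel_classify(clf, fv, operating_point)
  if (length(pred) != length(y)) stop("labels must align with feature rows")
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(precision = precision, recall = recall, f_score = f,
                 roc_auc = roc_auc(gel_score(clf, fv), y),
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 operating_point = operating_point,
                 threshold = clf$thresholds[[operating_point]]),
            class = "gel_eval")
}

#' @export
print.gel_eval <- function(x, ...) {
  cat(sprintf("<gel_eval @%.2f: P=%.3f R=%.3f F=%.3f AUC=%.3f (tp=%d fp=%d fn=%d tn=%d)>\n",
              x$threshold, x$precision, x$recall, x$f_score, x$roc_auc,
              x$confusion["tp"], x$confusion["fp"], x$confusion["fn"],
              x$confusion["tn"]))
  invisible(x)
}

MODEL_FORMAT_VERSION <- "gelminer-forest-1"

#' Persist / load a trained classifier (versioned JSON)
#'
#' The model file carries a format version, the feature schema and the
#' training metadata; loading a file with a different format version is an
#' error, and scoring with a mismatched feature schema is an error.
#'
#' @param clf a `gel_classifier`.
#' @param path JSON file path.
#' @export
save_gel_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "gel_classifier"))
  obj <- list(format = MODEL_FORMAT_VERSION,
              n_trees = clf$n_trees,
              thresholds = as.list(clf$thresholds),
              feature_names = clf$feature_names,
              training_meta = clf$training_meta,
              forest = clf$forest)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gel_classifier
#' @export
load_gel_classifier <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(j$format, MODEL_FORMAT_VERSION))
    stop("unsupported model format: ", j$format)
  forest <- lapply(j$forest, function(t)
    list(feat = as.integer(t$feat), thr = as.numeric(t$thr),
         left = as.integer(t$left), right = as.integer(t$right),
         pred = as.integer(t$pred)))
  structure(list(forest = forest,
                 n_trees = as.integer(j$n_trees),
                 thresholds = unlist(j$thresholds),
                 feature_names = j$feature_names,
                 training_meta = j$training_meta),
            class = "gel_classifier")
}
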