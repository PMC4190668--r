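#' Segmentation configuration
#'
#' @param binarize_threshold intensity in `[0,255]`, or `NULL` for automatic
#'   (Otsu) thresholding.
#' @param min_segment_area minimum connected-component size in pixels.
#' @param rect_edge_min_len minimum edge-run length (pixels) for the
#'   low-contrast rectangle detector.
#' @param rect_fill_tolerance maximum interior standard deviation of an
#'   accepted rectangle, as a fraction of 255.
#' @param ocr_enabled whether segment kinds are decided by the OCR adapter.
#' @return an object of class `gel_seg_config`.
#' @export
segmentation_config <- function(binarize_threshold = NULL,
                                min_segment_area = 100,
                                rect_edge_min_len = 40,
                                rect_fill_tolerance = 0.12,
                                ocr_enabled = TRUE) {
  stopifnot(min_segment_area >= 1,
            rect_fill_tolerance >= 0, rect_fill_tolerance <= 1)
  structure(list(binarize_threshold = binarize_threshold,
                 min_segment_area = min_segment_area,
                 rect_edge_min_len = rect_edge_min_len,
                 rect_fill_tolerance = rect_fill_tolerance,
                 ocr_enabled = ocr_enabled),
            class = "gel_seg_config")
}

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance over the 256-level histogram. Returns
#' the threshold `t`; foreground is `g <= t` for dark content on a light
#' background.
#'
#' @param g integer matrix in `[0, 255]`.
#' @return threshold intensity.
#' @export
otsu_threshold <- function(g) {
  counts <- tabulate(as.vector(g) + 1L, nbins = 256L)
  n <- sum(counts)
  lv <- 0:255
  n0 <- cumsum(counts)            # pixels at or below level t
  s0 <- cumsum(counts * lv)       # intensity sum at or below t
  n1 <- n - n0
  valid <- n0 > 0 & n1 > 0
  sigma_b <- rep(-1, 256)
  mu0 <- s0[valid] / n0[valid]
  mu1 <- (s0[256] - s0[valid]) / n1[valid]
  sigma_b[valid] <- (n0[valid] / n) * (n1[valid] / n) * (mu0 - mu1)^2
  which.max(sigma_b) - 1L
}

# Sobel gradients with clamped borders; returns list(gx, gy)
sobel <- function(g) {
  H <- nrow(g); W <- ncol(g)
  p <- g[c(1, 1:H, H), c(1, 1:W, W)]  # clamp-pad by 1
  sh <- function(dy, dx) p[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  list(gx = gx, gy = gy)
}

# decide TEXT vs GRAPHIC for a detected region via the OCR adapter:
# TEXT iff confidence >= 0.5 and at least one recognized character
classify_kind <- function(fig, b, ocr) {
  if (is.null(ocr)) return(list(kind = "GRAPHIC", text = ""))
  crop <- gray_pixels(crop_pixels(fig, b))
  attr(crop, "bbox") <- b
  res <- tryCatch(ocr(crop), error = function(e) list(text = "", confidence = 0))
  if (!is.null(res$confidence) && res$confidence >= 0.5 &&
      nchar(gsub("\\s", "", res$text)) >= 1) {
    list(kind = "TEXT", text = as.character(res$text))
  } else list(kind = "GRAPHIC", text = "")
}

#' Detect candidate segments (baseline connected-region detector)
#'
#' Binarizes the figure (Otsu by default, dark foreground) and returns
#' 4-connected foreground components of at least `min_segment_area` pixels
#' as segments, ordered top-to-bottom then left-to-right by bbox origin.
#' When an OCR adapter is supplied and `cfg$ocr_enabled` is true, a segment
#' is TEXT if the adapter recognizes at least one character at confidence
#' >= 0.5, else GRAPHIC.
#'
#' @param fig a [figure_image()].
#' @param cfg a [segmentation_config()].
#' @param ocr an OCR adapter or `NULL`.
#' @return list of [segment()]s (possibly empty).
#' @export
detect_segments <- function(fig, cfg = segmentation_config(), ocr = NULL) {
  g <- gray_pixels(fig)
  if (diff(range(g)) == 0) return(list())
  thr <- if (is.null(cfg$binarize_threshold)) otsu_threshold(g)
         else cfg$binarize_threshold
  mask <- g <= thr
  lab <- .label_components(mask)
  k <- max(lab)
  if (k < 1) return(list())
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1) %% nrow(g)       # 0-based
  cols <- (idx - 1) %/% nrow(g)
  count <- tabulate(l, nbins = k)
  y0 <- tapply(rows, l, min); y1 <- tapply(rows, l, max) + 1
  x0 <- tapply(cols, l, min); x1 <- tapply(cols, l, max) + 1
  keep <- which(count >= cfg$min_segment_area)
  if (!length(keep)) return(list())
  ord <- keep[order(y0[keep], x0[keep])]
  segs <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    j <- ord[i]
    b <- bbox(x0[[j]], y0[[j]], x1[[j]], y1[[j]])
    kd <- if (isTRUE(cfg$ocr_enabled)) classify_kind(fig, b, ocr)
          else list(kind = "GRAPHIC", text = "")
    segs[[i]] <- segment(sprintf("seg_%03d", i), b, kind = kd$kind,
                         text = kd$text, source = "SEGMENTATION")
  }
  segs
}

# long signed edge runs: for each row of `mask`, maximal TRUE runs of
# length >= min_len; adjacent-row duplicates (Sobel edges are two pixels
# thick) are collapsed keeping the larger row index
edge_runs <- function(mask, min_len) {
  out <- list()
  H <- nrow(mask)
  for (r in seq_len(H)) {
    v <- mask[r, ]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (j in which(rl$values & rl$lengths >= min_len)) {
      out[[length(out) + 1]] <- c(row = r - 1, s = starts[j] - 1, e = ends[j])
    }
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  m <- m[order(m[, "row"], m[, "s"]), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(m))) {
      if (i == j || !keep[j]) next
      if (m[j, "row"] > m[i, "row"] && m[j, "row"] - m[i, "row"] <= 2) {
        ov <- min(m[i, "e"], m[j, "e"]) - max(m[i, "s"], m[j, "s"])
        if (ov >= 0.8 * min(m[i, "e"] - m[i, "s"], m[j, "e"] - m[j, "s"]))
          keep[i] <- FALSE  # keep the lower (larger-row) duplicate
      }
    }
  }
  m[keep, , drop = FALSE]
}

#' Detect low-contrast rectangles
#'
#' Complementary detector for rectangles the binarization-based detector
#' misses because their interior barely contrasts with the surround (the
#' typical light-gray gel strip). Sobel edge maps are scanned for long
#' horizontal and vertical edge runs, runs are closed into axis-aligned
#' candidate boxes, and a candidate is accepted when its interior standard
#' deviation is at most `rect_fill_tolerance * 255`.
#'
#' @inheritParams detect_segments
#' @return list of GRAPHIC [segment()]s with source `"RECTANGLE_DETECTOR"`.
#' @export
detect_rectangles <- function(fig, cfg = segmentation_config()) {
  g <- gray_pixels(fig)
  H <- nrow(g); W <- ncol(g)
  if (diff(range(g)) == 0) return(list())
  sb <- sobel(g)
  edge_thr <- 80  # ~ intensity step of 20 under the Sobel 4x gain
  tops <- edge_runs(sb$gy <= -edge_thr, cfg$rect_edge_min_len)
  bots <- edge_runs(sb$gy >= edge_thr, cfg$rect_edge_min_len)
  # side edges may be much shorter than the long edges (gel strips are
  # wide and short); they only need to support a top/bottom pairing
  min_v <- max(8, cfg$rect_edge_min_len %/% 4)
  lefts <- edge_runs(t(sb$gx <= -edge_thr), min_v)
  rights <- edge_runs(t(sb$gx >= edge_thr), min_v)
  if (is.null(tops) || is.null(bots) || is.null(lefts) || is.null(rights))
    return(list())
  boxes <- list()
  find_vertical <- function(runs, col, yy0, yy1) {
    hh <- yy1 - yy0
    for (i in seq_len(nrow(runs))) {
      if (abs(runs[i, "row"] - col) > 4) next
      ov <- min(runs[i, "e"], yy1) - max(runs[i, "s"], yy0)
      if (ov >= 0.6 * hh) return(runs[i, "row"])
    }
    NA
  }
  for (i in seq_len(nrow(tops))) for (j in seq_len(nrow(bots))) {
    y0 <- tops[i, "row"]; y1 <- bots[j, "row"]
    if (y1 - y0 < 8) next
    s <- max(tops[i, "s"], bots[j, "s"]); e <- min(tops[i, "e"], bots[j, "e"])
    if (e - s < cfg$rect_edge_min_len) next
    len_t <- tops[i, "e"] - tops[i, "s"]; len_b <- bots[j, "e"] - bots[j, "s"]
    if (e - s < 0.7 * max(len_t, len_b)) next
    x0 <- find_vertical(lefts, s, y0, y1)
    x1 <- find_vertical(rights, e, y0, y1)
    if (is.na(x0) || is.na(x1) || x1 - x0 < 8) next
    x0 <- max(0, x0); x1 <- min(W, x1); y1 <- min(H, y1)
    # interior uniformity, measured 3 px inside the border
    iy0 <- y0 + 3; iy1 <- y1 - 3; ix0 <- x0 + 3; ix1 <- x1 - 3
    if (iy1 - iy0 < 2 || ix1 - ix0 < 2) next
    interior <- g[(iy0 + 1):iy1, (ix0 + 1):ix1]
    if (sd(as.numeric(interior)) > cfg$rect_fill_tolerance * 255) next
    boxes[[length(boxes) + 1]] <- c(x0, y0, x1, y1)
  }
  if (!length(boxes)) return(list())
  # duplicate suppression among candidates (keep first = topmost pairing)
  keep <- list()
  for (b in boxes) {
    dup <- any(vapply(keep, function(kb) bbox_iou(kb, b) > 0.8, TRUE))
    if (!dup) keep[[length(keep) + 1]] <- b
  }
  keep <- keep[order(vapply(keep, `[[`, 0, 2), vapply(keep, `[[`, 0, 1))]
  lapply(seq_along(keep), function(i)
    segment(sprintf("rect_%03d", i), bbox(keep[[i]][1], keep[[i]][2],
                                          keep[[i]][3], keep[[i]][4]),
            kind = "GRAPHIC", source = "RECTANGLE_DETECTOR"))
}

#' Full segmentation pass
#'
#' Runs [detect_segments()] and [detect_rectangles()] and merges the two
#' candidate sets: when a connected-region segment and a detected rectangle
#' overlap with IoU > 0.8 the rectangle-detector box wins. Segment ids are
#' reassigned in reading order.
#'
#' @inheritParams detect_segments
#' @return list of [segment()]s.
#' @export
segment_figure <- function(fig, cfg = segmentation_config(), ocr = NULL) {
  base <- detect_segments(fig, cfg, ocr)
  rects <- detect_rectangles(fig, cfg)
  for (r in rects) {
    matched <- FALSE
    for (i in seq_along(base)) {
      if (bbox_iou(base[[i]]$bbox, r$bbox) > 0.8) {
        base[[i]]$bbox <- r$bbox
        base[[i]]$source <- "RECTANGLE_DETECTOR"
        matched <- TRUE
        break
      }
    }
    if (!matched) base[[length(base) + 1]] <- r
  }
  if (!length(base)) return(base)
  ord <- order(vapply(base, function(s) s$bbox[[2]], 0),
               vapply(base, function(s) s$bbox[[1]], 0))
  base <- base[ord]
  for (i in seq_along(base)) base[[i]]$segment_id <- sprintf("seg_%03d", i)
  base
}
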