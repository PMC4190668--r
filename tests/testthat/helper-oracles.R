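# Independent oracles and shared fixtures. Oracles deliberately use
# different formulations than the package internals (pixel enumeration,
# area arithmetic, BFS) so agreement is evidence, not tautology.

# ---- geometry oracles ------------------------------------------------------

# boxes are treated as closed rectangles [x0,x1] x [y0,y1]; the minimum
# distance between two axis-aligned rectangles is attained at points with
# integer coordinates when the corners are integers, so enumerating the
# integer boundary points is exact
oracle_boundary_points <- function(b) {
  xs <- b[1]:b[3]; ys <- b[2]:b[4]
  rbind(cbind(xs, b[2]), cbind(xs, b[4]), cbind(b[1], ys), cbind(b[3], ys))
}

oracle_box_distance <- function(a, b) {
  pa <- oracle_boundary_points(a); pb <- oracle_boundary_points(b)
  # overlap: some pixel covered by both -> 0
  if (max(a[1], b[1]) <= min(a[3], b[3]) && max(a[2], b[2]) <= min(a[4], b[4]))
    return(0)
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
  sqrt(min(d2))
}

# interval-gap formulation (independent derivation of closest-point dist)
oracle_gap_distance <- function(a, b) {
  dx <- max(a[1] - b[3], b[1] - a[3], 0)
  dy <- max(a[2] - b[4], b[2] - a[4], 0)
  sqrt(dx^2 + dy^2)
}

# pixel-enumeration corridor check: is any pixel of `txt` inside
# hull(a, b) but outside both a and b? (pixel (x, y) lies in box iff
# x0 <= x < x1, y0 <= y < y1)
oracle_text_between_pixels <- function(a, b, txt) {
  hull <- c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
  xs <- seq(max(txt[1], hull[1]), min(txt[3], hull[3]) - 1)
  ys <- seq(max(txt[2], hull[2]), min(txt[4], hull[4]) - 1)
  if (!length(xs) || !length(ys) || xs[1] > xs[length(xs)] ||
      ys[1] > ys[length(ys)]) return(FALSE)
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  in_a <- px >= a[1] & px < a[3] & py >= a[2] & py < a[4]
  in_b <- px >= b[1] & px < b[3] & py >= b[2] & py < b[4]
  any(!in_a & !in_b)
}

# area-arithmetic corridor check (closed form, also independent):
# area(T on H) > area(T on A) + area(T on B) - area(T on A on B)
oracle_text_between_area <- function(a, b, txt) {
  iarea <- function(p, q) {
    w <- min(p[3], q[3]) - max(p[1], q[1])
    h <- min(p[4], q[4]) - max(p[2], q[2])
    if (w <= 0 || h <= 0) 0 else w * h
  }
  hull <- c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
  iab <- c(max(a[1], b[1]), max(a[2], b[2]), min(a[3], b[3]), min(a[4], b[4]))
  covered <- iarea(txt, a) + iarea(txt, b) -
    (if (iab[3] > iab[1] && iab[4] > iab[2]) iarea(txt, iab) else 0)
  iarea(txt, hull) > covered
}

# distance from an integer point to the border of a box, independently:
# outside -> hypot of positive axis gaps; inside -> smallest slack
oracle_point_border <- function(px, py, b) {
  dx <- max(b[1] - px, px - b[3]); dy <- max(b[2] - py, py - b[4])
  if (dx <= 0 && dy <= 0) return(-max(dx, dy))
  sqrt(max(0, dx)^2 + max(0, dy)^2)
}

oracle_attribute <- function(region, txt, near_px = 30, far_px = 150) {
  if (oracle_gap_distance(txt, region) > near_px) return(FALSE)
  corners <- rbind(c(txt[1], txt[2]), c(txt[3], txt[2]),
                   c(txt[1], txt[4]), c(txt[3], txt[4]))
  far <- max(apply(corners, 1, function(p)
    oracle_point_border(p[1], p[2], region)))
  far <= far_px
}

# exhaustive connected components by BFS over an adjacency matrix
oracle_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; comp <- integer(0)
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# pure-R flood-fill 4-connected labeling (small fixtures only)
oracle_flood_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (x in seq_len(W)) for (y in seq_len(H)) {
    if (!mask[y, x] || lab[y, x] > 0) next
    nxt <- nxt + 1L
    stack <- list(c(y, x))
    lab[y, x] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        yy <- p[1] + d[1]; xx <- p[2] + d[2]
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
            mask[yy, xx] && lab[yy, xx] == 0) {
          lab[yy, xx] <- nxt
          stack[[length(stack) + 1]] <- c(yy, xx)
        }
      }
    }
  }
  lab
}

# per-pixel histogram counting (oracle for histogram_features)
oracle_hist16 <- function(g) {
  counts <- numeric(16)
  for (v in as.vector(g)) {
    b <- if (v >= 240) 16 else v %/% 16 + 1
    counts[b] <- counts[b] + 1
  }
  counts / length(g)
}

# ---- synthetic-score classifier -------------------------------------------

# a gel_classifier whose score equals the (single) feature value, built
# from hand-made threshold-stump trees; feature values on multiples of
# 1/n_steps are reproduced exactly
make_score_classifier <- function(n_steps = 20) {
  trees <- lapply(seq_len(n_steps), function(t) {
    list(feat = c(0L, -1L, -1L), thr = c((t - 0.5) / n_steps, 0, 0),
         left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
         pred = c(0L, 0L, 1L))
  })
  structure(list(forest = trees, n_trees = n_steps,
                 thresholds = gel_thresholds(), feature_names = NULL,
                 training_meta = list(n_samples = 0, class_balance = NA,
                                      seed = 0)),
            class = "gel_classifier")
}

# layout sampler shared by the grouping/attribution oracle suites
random_layout <- function() {
  n_box <- sample(3:15, 1)
  boxes <- lapply(seq_len(n_box), function(i) {
    x0 <- sample(0:340, 1); y0 <- sample(0:260, 1)
    c(x0, y0, x0 + sample(10:60, 1), y0 + sample(8:40, 1))
  })
  scores <- sample(seq(0, 1, by = 0.05), n_box, replace = TRUE)
  n_text <- sample(0:3, 1)
  texts <- lapply(seq_len(n_text), function(i) {
    x0 <- sample(0:360, 1); y0 <- sample(0:280, 1)
    c(x0, y0, x0 + sample(15:70, 1), y0 + sample(6:16, 1))
  })
  list(boxes = boxes, scores = scores, texts = texts)
}

layout_segments <- function(layout) {
  segs <- lapply(seq_along(layout$boxes), function(i)
    segment(sprintf("g%02d", i), bbox(layout$boxes[[i]][1],
                                      layout$boxes[[i]][2],
                                      layout$boxes[[i]][3],
                                      layout$boxes[[i]][4]),
            kind = "GRAPHIC"))
  texts <- lapply(seq_along(layout$texts), function(i)
    segment(sprintf("t%02d", i), bbox(layout$texts[[i]][1],
                                      layout$texts[[i]][2],
                                      layout$texts[[i]][3],
                                      layout$texts[[i]][4]),
            kind = "TEXT", text = "x"))
  c(segs, texts)
}

layout_features <- function(layout) {
  m <- matrix(layout$scores, ncol = 1)
  rownames(m) <- sprintf("g%02d", seq_along(layout$scores))
  m
}

# oracle grouping for a layout: components of the (<= adj px, no text
# between) relation over high-recall positives, kept iff a high-precision
# member exists
oracle_grouping <- function(layout, adjacency_px = 50, thresholds = gel_thresholds()) {
  hr <- which(layout$scores >= thresholds[["high_recall"]])
  if (!length(hr)) return(list())
  k <- length(hr)
  adj <- matrix(FALSE, k, k)
  if (k >= 2) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    a <- layout$boxes[[hr[i]]]; b <- layout$boxes[[hr[j]]]
    ok <- oracle_gap_distance(a, b) <= adjacency_px &&
      !any(vapply(layout$texts, function(t)
        oracle_text_between_area(a, b, t), TRUE))
    adj[i, j] <- adj[j, i] <- ok
  }
  comps <- oracle_components(adj)
  comps <- Filter(function(ix)
    any(layout$scores[hr[ix]] >= thresholds[["high_precision"]]), comps)
  comps <- lapply(comps, function(ix) sprintf("g%02d", sort(hr[ix])))
  comps[order(vapply(comps, `[[`, "", 1))]
}

# ---- demo classifier trained on synthetic figures (memoized) ---------------

.demo_env <- new.env(parent = emptyenv())

demo_classifier <- function() {
  if (is.null(.demo_env$clf)) {
    figs <- generate_figures(generator_config(seed = 7001, n_figures = 30))
    X <- list(); y <- list()
    for (fa in figs) {
      X[[length(X) + 1]] <- feature_matrix(fa$figure, fa$annotation$segments)
      y[[length(y) + 1]] <- vapply(fa$annotation$segments,
                                   function(s) isTRUE(s$is_gel), TRUE)
    }
    .demo_env$clf <- gel_train(do.call(rbind, X), unlist(y), seed = 11)
  }
  .demo_env$clf
}

# labeled segment-level features for a generated figure set
labeled_features <- function(figs) {
  X <- list(); y <- list()
  for (fa in figs) {
    X[[length(X) + 1]] <- feature_matrix(fa$figure, fa$annotation$segments)
    y[[length(y) + 1]] <- vapply(fa$annotation$segments,
                                 function(s) isTRUE(s$is_gel), TRUE)
  }
  list(x = do.call(rbind, X), y = unlist(y))
}

gold_panel_regions <- function(ann) {
  ids <- vapply(ann$segments, function(s) s$segment_id, "")
  lapply(ann$panels, function(p) {
    m <- do.call(rbind, lapply(ann$segments[match(p$members, ids)],
                               function(s) s$bbox))
    c(min(m[, 1]), min(m[, 2]), max(m[, 3]), max(m[, 4]))
  })
}
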