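# Seeded synthetic-figure generator with exact ground truth. It emulates
# the image classes the detector must separate: gel strips (rectangles
# with dark blurred bands on a light gray background, or the inverted
# white-on-black variant), distractor panels (bar graphs, line graphs,
# photo-like patches, text blocks) and text labels rendered with the
# bundled bitmap font. Ground-truth panels always satisfy the detection
# geometry (members <= 50 px apart with no text between; gold labels
# within the 30/150 px window), so a perfect pipeline can reach recall 1
# in the noiseless setting.

#' Generator configuration
#'
#' @param seed corpus-level RNG seed; per-figure seeds are derived from it.
#' @param n_figures number of figures.
#' @param figure_size `c(width, height)` in pixels.
#' @param gel_style `"DARK_ON_LIGHT"`, `"WHITE_ON_BLACK"` or `"MIXED"`.
#' @param panel_rows,panel_cols ranges of gel-grid dimensions.
#' @param band_count range of band counts per gel segment.
#' @param noise_sd additive Gaussian pixel noise (intensity units).
#' @param p_gel_figure probability that a figure contains a gel panel;
#'   with the default distractor load this keeps gel segments a small
#'   minority of all graphic segments.
#' @param distractor_mix fractions over the four distractor types
#'   (must sum to 1).
#' @param n_distractors range of distractor panels per figure.
#' @param label_pool strings sampled for gel labels (gene-symbol-like
#'   tokens, cell-line names, and "+"/"-" condition rows).
#' @return an object of class `gel_generator_config`.
#' @export
generator_config <- function(seed = 42, n_figures = 10,
                             figure_size = c(480, 360),
                             gel_style = c("MIXED", "DARK_ON_LIGHT",
                                           "WHITE_ON_BLACK"),
                             panel_rows = 1:2, panel_cols = 2:4,
                             band_count = c(1, 8),
                             noise_sd = 2,
                             p_gel_figure = 0.25,
                             distractor_mix = c(bar_graph = 0.30,
                                                line_graph = 0.25,
                                                photo_like = 0.20,
                                                text_block = 0.25),
                             n_distractors = c(4, 7),
                             label_pool = NULL) {
  gel_style <- match.arg(gel_style)
  stopifnot(abs(sum(distractor_mix) - 1) < 1e-9,
            length(panel_rows) >= 1, length(panel_cols) >= 1,
            band_count[1] >= 1, band_count[2] >= band_count[1],
            noise_sd >= 0, p_gel_figure >= 0, p_gel_figure <= 1)
  if (is.null(label_pool))
    label_pool <- c("LOX", "NHEM", "ACTB", "GAPDH", "TP53", "EGFR", "MYC",
                    "KRAS", "STAT3", "AKT1", "BCL2", "BAX", "CDK2", "VIM",
                    "SRC", "JUN", "FOS", "KIT", "TNF", "IL6",
                    "MDA-MB-231", "C8161.9", "HELA", "24 HRS", "CONTROL",
                    "+", "-", "+ -", "- +", "+ +")
  structure(list(seed = as.integer(seed), n_figures = as.integer(n_figures),
                 figure_size = figure_size, gel_style = gel_style,
                 panel_rows = panel_rows, panel_cols = panel_cols,
                 band_count = band_count, noise_sd = noise_sd,
                 p_gel_figure = p_gel_figure,
                 distractor_mix = distractor_mix,
                 n_distractors = n_distractors,
                 label_pool = label_pool),
            class = "gel_generator_config")
}

# sample one element of a vector (safe for length-1 vectors, unlike sample())
pick <- function(v) v[sample.int(length(v), 1)]

clamp255 <- function(m) {
  m[m < 0] <- 0; m[m > 255] <- 255
  m <- round(m)
  storage.mode(m) <- "integer"
  m
}

gauss_kernel <- function(sigma) {
  r <- max(1, ceiling(2.5 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Generate one synthetic gel segment
#'
#' A light-gray rectangle (background ~180-220) with 1-8 dark blurred
#' elliptical bands in a lane layout; `WHITE_ON_BLACK` is the exact
#' inversion (`255 - patch`) of the patch generated from the same RNG
#' state. Consumes the current RNG stream; seed it for reproducibility.
#'
#' @param cfg a [generator_config()].
#' @param style gel rendering style; `"MIXED"` is resolved by the caller.
#' @param w,h patch size in pixels (randomized when `NULL`).
#' @return `list(pixels = <integer matrix>, truth = <list>)`; the truth
#'   record holds style, background intensity and a band table
#'   (`cx, cy, rx, ry, depth`).
#' @export
generate_gel_segment <- function(cfg = generator_config(),
                                 style = c("DARK_ON_LIGHT", "WHITE_ON_BLACK"),
                                 w = NULL, h = NULL) {
  style <- match.arg(style)
  if (is.null(w)) w <- pick(70:140)
  if (is.null(h)) h <- pick(28:56)
  bg <- runif(1, 180, 220)
  n_bands <- pick(seq(cfg$band_count[1], cfg$band_count[2]))
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), w), h, w)
  field <- matrix(0, h, w)
  bands <- data.frame(cx = numeric(n_bands), cy = numeric(n_bands),
                      rx = numeric(n_bands), ry = numeric(n_bands),
                      depth = numeric(n_bands))
  for (i in seq_len(n_bands)) {
    cx <- (i - 0.5) / n_bands * w + runif(1, -0.1, 0.1) * w / n_bands
    cy <- h * runif(1, 0.4, 0.6)
    rx <- max(3, w / (2.6 * n_bands) * runif(1, 0.65, 1))
    ry <- max(3, h * runif(1, 0.14, 0.24))
    depth <- runif(1, 60, 140)
    ell <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
    field <- pmax(field, depth * ell)
    bands[i, ] <- c(cx, cy, rx, ry, depth)
  }
  field <- .conv_sep(field, gauss_kernel(1.2))
  patch <- clamp255(bg - field)
  if (style == "WHITE_ON_BLACK") patch <- 255L - patch
  list(pixels = patch,
       truth = list(style = style, bg = bg, w = w, h = h, bands = bands))
}

render_bar_graph <- function(w, h) {
  m <- matrix(255L, h, w)
  m[, 8:9] <- 40L                  # y axis
  m[(h - 9):(h - 8), ] <- 40L      # x axis
  nb <- sample(4:7, 1)
  slot <- (w - 24) / nb
  bw <- max(4, floor(slot * 0.55))
  fill <- sample(30:90, 1)
  for (i in seq_len(nb)) {
    x0 <- round(12 + (i - 1) * slot + (slot - bw) / 2)
    bh <- round(runif(1, 0.25, 0.9) * (h - 18))
    m[(h - 9 - bh):(h - 10), (x0 + 1):(x0 + bw)] <- as.integer(fill)
  }
  m
}

render_line_graph <- function(w, h) {
  m <- matrix(255L, h, w)
  m[, 8:9] <- 40L
  m[(h - 9):(h - 8), ] <- 40L
  y <- h / 2
  for (x in 12:(w - 3)) {
    y <- min(max(y + rnorm(1, 0, 2.5), 8), h - 12)
    m[round(y):(round(y) + 1), x] <- 20L
  }
  m
}

render_photo_like <- function(w, h) {
  noise <- matrix(runif(w * h), h, w)
  sm <- .conv_sep(noise, gauss_kernel(4))
  sm <- (sm - min(sm)) / max(1e-12, diff(range(sm)))
  clamp255(20 + 215 * sm)
}

render_text_block <- function(pool) {
  n_lines <- sample(2:4, 1)
  lines <- replicate(n_lines,
    paste(sample(pool, sample(1:2, 1), replace = TRUE), collapse = " "))
  mats <- lapply(lines, render_text, scale = 1, pad = 1)
  w <- max(vapply(mats, ncol, 0L))
  rows <- lapply(mats, function(m) {
    out <- matrix(255L, nrow(m) + 2, w)
    out[1:nrow(m), 1:ncol(m)] <- m
    out
  })
  list(pixels = do.call(rbind, rows), text = paste(lines, collapse = " "))
}

# expand a box by `by` px on all sides (clamped at 0)
inflate <- function(b, by) c(max(0, b[1] - by), max(0, b[2] - by),
                             b[3] + by, b[4] + by)

overlaps_any <- function(b, boxes, margin = 12) {
  bi <- inflate(b, margin)
  for (o in boxes) if (!is.null(bbox_intersect(bi, o))) return(TRUE)
  FALSE
}

# derived per-figure seed, kept below 2^31
figure_seed <- function(seed, index) {
  (as.numeric(seed) * 131071 + as.numeric(index) * 9973) %% 2147483647
}

#' Generate one synthetic figure with ground truth
#'
#' Lays out at most one gel panel (an r x c grid of gel strips with <= 50
#' px gaps, column labels above and row labels left, all inside the 30/150
#' px attribution window) plus distractor panels and decoy labels placed
#' outside the attribution window, on a white canvas without overlap.
#' Deterministic for fixed `(cfg, index)`.
#'
#' @param cfg a [generator_config()].
#' @param index figure index (drives the derived seed and the image id).
#' @return `list(figure = <gel_figure>, annotation = <gel_annotation>)`.
#' @export
generate_figure <- function(cfg = generator_config(), index = 1) {
  set.seed(figure_seed(cfg$seed, index))
  W <- cfg$figure_size[1]; H <- cfg$figure_size[2]
  canvas <- matrix(255L, H, W)
  segs <- list()
  boxes <- list()  # occupied boxes (for overlap rejection)
  panels <- list()
  place <- function(patch, b) {
    canvas[(b[2] + 1):b[4], (b[1] + 1):b[3]] <<- patch
    boxes[[length(boxes) + 1]] <<- b
  }
  gel_region <- NULL
  has_gel <- runif(1) < cfg$p_gel_figure
  if (has_gel) {
    style <- if (cfg$gel_style == "MIXED")
      sample(c("DARK_ON_LIGHT", "WHITE_ON_BLACK"), 1, prob = c(0.8, 0.2))
    else cfg$gel_style
    r <- pick(cfg$panel_rows); cc <- pick(cfg$panel_cols)
    gx <- pick(8:30); gy <- pick(8:30)
    w0_max <- floor((W - 120 - (cc - 1) * gx) / cc)
    h0_max <- floor((H - 80 - (r - 1) * gy) / r)
    if (w0_max < 40 || h0_max < 26)
      stop("infeasible gel layout for figure size")
    w0 <- pick(seq(40, min(100, w0_max)))
    h0 <- pick(seq(26, min(40, h0_max)))
    tw <- cc * w0 + (cc - 1) * gx
    th <- r * h0 + (r - 1) * gy
    x0 <- pick(100:(W - tw - 10))
    y0 <- pick(60:(H - th - 10))
    gel_ids <- character(0)
    for (i in seq_len(r)) for (j in seq_len(cc)) {
      gs <- generate_gel_segment(cfg, style, w = w0, h = h0)
      bx <- c(x0 + (j - 1) * (w0 + gx), y0 + (i - 1) * (h0 + gy))
      b <- c(bx[1], bx[2], bx[1] + w0, bx[2] + h0)
      place(gs$pixels, b)
      id <- sprintf("gel_%d_%d", i, j)
      gel_ids <- c(gel_ids, id)
      segs[[length(segs) + 1]] <-
        segment(id, bbox(b[1], b[2], b[3], b[4]), kind = "GRAPHIC",
                source = "ANNOTATION", is_gel = TRUE)
    }
    gel_region <- c(x0, y0, x0 + tw, y0 + th)
    # column labels above the grid, row labels to the left; gaps keep the
    # nearest edge <= 30 px and the farthest corner <= 150 px
    label_ids <- character(0)
    # column labels must fit one grid pitch so neighbors cannot collide
    pitch <- w0 + gx
    short_pool <- cfg$label_pool[
      nchar(cfg$label_pool) <= max(1, floor((pitch - 4) / 12))]
    if (!length(short_pool)) short_pool <- c("+", "-")
    for (j in seq_len(cc)) {
      txt <- pick(short_pool)
      tm <- render_text(txt, scale = 2, pad = 1)
      g <- pick(6:22)
      lw <- ncol(tm); lh <- nrow(tm)
      lx <- min(max(0, x0 + (j - 1) * (w0 + gx) + round((w0 - lw) / 2)), W - lw)
      ly <- y0 - g - lh
      if (ly < 0) next
      b <- c(lx, ly, lx + lw, ly + lh)
      place(tm, b)
      id <- sprintf("collab_%d", j)
      label_ids <- c(label_ids, id)
      segs[[length(segs) + 1]] <-
        segment(id, bbox(b[1], b[2], b[3], b[4]), kind = "TEXT",
                text = txt, source = "ANNOTATION", is_gel = FALSE)
    }
    for (i in seq_len(r)) {
      txt <- pick(c("+", "-", pick(short_pool)))
      tm <- render_text(txt, scale = 2, pad = 1)
      g <- pick(6:22)
      lw <- ncol(tm); lh <- nrow(tm)
      lx <- x0 - g - lw
      ly <- min(max(0, y0 + (i - 1) * (h0 + gy) + round((h0 - lh) / 2)), H - lh)
      if (lx < 0) next
      b <- c(lx, ly, lx + lw, ly + lh)
      place(tm, b)
      id <- sprintf("rowlab_%d", i)
      label_ids <- c(label_ids, id)
      segs[[length(segs) + 1]] <-
        segment(id, bbox(b[1], b[2], b[3], b[4]), kind = "TEXT",
                text = txt, source = "ANNOTATION", is_gel = FALSE)
    }
    panels[[1]] <- list(members = gel_ids, labels = label_ids)
  }
  # distractor panels, kept >= 60 px from the gel region so classifier
  # false positives next to a gel cannot silently join the gold panel
  nd <- pick(seq(cfg$n_distractors[1], cfg$n_distractors[2]))
  types <- sample(names(cfg$distractor_mix), nd, replace = TRUE,
                  prob = cfg$distractor_mix)
  for (k in seq_len(nd)) {
    ty <- types[k]
    txt <- ""
    if (ty == "bar_graph") {
      patch <- render_bar_graph(pick(80:140), pick(60:100))
    } else if (ty == "line_graph") {
      patch <- render_line_graph(pick(80:140), pick(60:100))
    } else if (ty == "photo_like") {
      patch <- render_photo_like(pick(70:120), pick(60:110))
    } else {
      tb <- render_text_block(cfg$label_pool)
      patch <- tb$pixels; txt <- tb$text
    }
    ph <- nrow(patch); pw <- ncol(patch)
    for (try in 1:300) {
      x <- pick(0:(W - pw)); y <- pick(0:(H - ph))
      b <- c(x, y, x + pw, y + ph)
      if (overlaps_any(b, boxes)) next
      if (!is.null(gel_region) && segment_distance(b, gel_region) < 60) next
      place(patch, b)
      id <- sprintf("dis_%s_%d", ty, k)
      segs[[length(segs) + 1]] <- segment(
        id, bbox(b[1], b[2], b[3], b[4]),
        kind = if (ty == "text_block") "TEXT" else "GRAPHIC",
        text = if (ty == "text_block") txt else "",
        source = "ANNOTATION", is_gel = FALSE)
      break
    }
    # placement is best-effort: crowded canvases simply get fewer
    # distractors, as real multi-panel figures vary in panel count
  }
  if (!has_gel && !length(segs))
    stop("infeasible layout: empty figure after bounded retries")
  # decoy labels: text near-ish the gel but outside the 30/150 window
  # (nearest edge > 30 px), and free-floating text when there is no gel
  n_decoy <- pick(1:3)
  for (k in seq_len(n_decoy)) {
    txt <- pick(cfg$label_pool)
    tm <- render_text(txt, scale = 2, pad = 1)
    ph <- nrow(tm); pw <- ncol(tm)
    for (try in 1:300) {
      x <- pick(0:(W - pw)); y <- pick(0:(H - ph))
      b <- c(x, y, x + pw, y + ph)
      if (overlaps_any(b, boxes)) next
      if (!is.null(gel_region) && segment_distance(b, gel_region) <= 40) next
      place(tm, b)
      segs[[length(segs) + 1]] <- segment(
        sprintf("decoy_%d", k), bbox(b[1], b[2], b[3], b[4]), kind = "TEXT",
        text = txt, source = "ANNOTATION", is_gel = FALSE)
      break
    }
  }
  if (cfg$noise_sd > 0)
    canvas <- clamp255(canvas + rnorm(length(canvas), 0, cfg$noise_sd))
  image_id <- sprintf("synth_%04d", index)
  list(figure = figure_image(canvas, image_id),
       annotation = figure_annotation(image_id, segs, panels))
}

#' Generate a list of figures in memory
#' @inheritParams generate_figure
#' @return list of `list(figure, annotation)` of length `cfg$n_figures`.
#' @export
generate_figures <- function(cfg = generator_config()) {
  lapply(seq_len(cfg$n_figures), function(i) generate_figure(cfg, i))
}

#' Generate a corpus on disk
#'
#' Writes `synth_NNNN.png` + `synth_NNNN.json` (ground-truth annotation)
#' pairs plus a `manifest.json` echoing the configuration and per-figure
#' truth summaries. Fully deterministic under a fixed seed.
#'
#' @param cfg a [generator_config()].
#' @param out_dir writable output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
generate_corpus <- function(cfg = generator_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- vector("list", cfg$n_figures)
  for (i in seq_len(cfg$n_figures)) {
    fa <- generate_figure(cfg, i)
    write_figure(fa$figure, file.path(out_dir, paste0(fa$figure$image_id, ".png")))
    write_annotation(fa$annotation,
                     file.path(out_dir, paste0(fa$figure$image_id, ".json")))
    gels <- vapply(fa$annotation$segments, function(s) isTRUE(s$is_gel), TRUE)
    graphics <- vapply(fa$annotation$segments,
                       function(s) s$kind == "GRAPHIC", TRUE)
    summaries[[i]] <- list(image_id = fa$figure$image_id,
                           n_segments = length(fa$annotation$segments),
                           n_graphic_segments = sum(graphics),
                           n_gel_segments = sum(gels),
                           n_panels = length(fa$annotation$panels))
  }
  cfg_echo <- unclass(cfg)
  manifest <- list(config = cfg_echo,
                   n_figures = cfg$n_figures,
                   gel_segment_fraction =
                     sum(vapply(summaries, `[[`, 0, "n_gel_segments")) /
                     max(1, sum(vapply(summaries, `[[`, 0, "n_graphic_segments"))),
                   figures = summaries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
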