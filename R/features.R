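# The 39 segment descriptors fed to the gel classifier:
#   2 relative position (bbox center / image size)
#   2 relative width/height + 2 absolute width/height
#  16 normalized grayscale histogram bins
#   3 color features (mean R, G, B)
#  13 texture features: 6 Tamura-style statistics (coarseness, contrast,
#     directionality, line-likeness, regularity, roughness) + 7 log-spaced
#     radial spectral-power bands ("ripples")
#   1 count of recognized characters

FEATURE_NAMES <- c(
  "rel_x", "rel_y", "rel_w", "rel_h", "abs_w", "abs_h",
  sprintf("hist_%02d", 1:16),
  "color_r", "color_g", "color_b",
  "coarseness", "contrast", "directionality", "line_likeness",
  "regularity", "roughness", sprintf("ripple_%d", 1:7),
  "n_chars")

#' Names of the 39 segment features
#' @return character vector of length 39.
#' @export
feature_names <- function() FEATURE_NAMES

#' Grayscale histogram features
#'
#' 16 equal-width bins over `[0, 255]`: bin `b` counts intensities in
#' `[16(b-1), 16b)` with the last bin closed at 255, normalized by pixel
#' count so the features are scale-free in area.
#'
#' @param g integer grayscale matrix/vector in `[0, 255]`.
#' @return numeric vector of 16 fractions summing to 1.
#' @export
histogram_features <- function(g) {
  v <- as.vector(g)
  if (!length(v)) stop("empty region has no histogram")
  bins <- pmin(v %/% 16L, 15L) + 1L
  tabulate(bins, nbins = 16L) / length(v)
}

# mean over all wsize x wsize windows via integral image (clamped borders)
box_mean <- function(g, half) {
  k <- rep(1 / (2 * half), 2 * half)
  .conv_sep(g, k)
}

tamura_coarseness <- function(g) {
  H <- nrow(g); W <- ncol(g)
  kmax <- max(1, min(5, floor(log2(min(H, W))) - 1))
  best_e <- matrix(-Inf, H, W)
  best_s <- matrix(1, H, W)
  for (k in seq_len(kmax)) {
    half <- 2^(k - 1)
    a <- box_mean(g, half)
    # horizontal / vertical mean differences at offset 2^(k-1)
    sh <- function(m, dy, dx) {
      ri <- pmin(pmax(seq_len(H) + dy, 1), H)
      ci <- pmin(pmax(seq_len(W) + dx, 1), W)
      m[ri, ci, drop = FALSE]
    }
    eh <- abs(sh(a, 0, half) - sh(a, 0, -half))
    ev <- abs(sh(a, half, 0) - sh(a, -half, 0))
    e <- pmax(eh, ev)
    upd <- e > best_e
    best_e[upd] <- e[upd]
    best_s[upd] <- 2^k
  }
  mean(best_s)
}

tamura_contrast <- function(v) {
  s2 <- mean((v - mean(v))^2)
  if (s2 == 0) return(0)
  m4 <- mean((v - mean(v))^4)
  kurt <- m4 / s2^2
  sqrt(s2) / kurt^0.25
}

# gradient direction statistics; returns directionality (histogram energy,
# high = strongly oriented) and line-likeness (direction co-occurrence
# along the edge direction at offset 4 px)
direction_stats <- function(g) {
  H <- nrow(g); W <- ncol(g)
  if (H < 3 || W < 3) return(c(directionality = 0, line_likeness = 0))
  gx <- g[, c(2:W, W), drop = FALSE] - g[, c(1, 1:(W - 1)), drop = FALSE]
  gy <- g[c(2:H, H), , drop = FALSE] - g[c(1, 1:(H - 1)), , drop = FALSE]
  mag <- abs(gx) + abs(gy)
  strong <- mag >= 16
  if (!any(strong)) return(c(directionality = 0, line_likeness = 0))
  nb <- 16L
  theta <- atan2(gy, gx) %% pi
  bin <- pmin(floor(theta / pi * nb), nb - 1) + 1
  p <- tabulate(bin[strong], nbins = nb)
  p <- p / sum(p)
  directionality <- sum(p^2)
  # co-occurrence: direction at p vs direction 4 px away along p's direction
  d <- 4
  idx <- which(strong)
  rr <- (idx - 1) %% H + 1
  cc <- (idx - 1) %/% H + 1
  th <- theta[idx]
  r2 <- pmin(pmax(rr + round(sin(th) * d), 1), H)
  c2 <- pmin(pmax(cc + round(cos(th) * d), 1), W)
  j <- (c2 - 1) * H + r2
  ok <- strong[j]
  if (!any(ok)) return(c(directionality = directionality, line_likeness = 0))
  delta <- (bin[idx[ok]] - bin[j[ok]]) * 2 * pi / nb
  c(directionality = directionality, line_likeness = mean(cos(delta)))
}

# 7 log-spaced radial power bands of the centered 2-D spectrum; fractions
# of total AC power, all zero for a constant patch
ripple_bands <- function(g) {
  H <- nrow(g); W <- ncol(g)
  z <- g - mean(g)
  if (all(z == 0)) return(rep(0, 7))
  P <- Mod(fft(z))^2
  fy <- pmin(0:(H - 1), H - (0:(H - 1))) / H
  fx <- pmin(0:(W - 1), W - (0:(W - 1))) / W
  r <- sqrt(outer(fy^2, fx^2, `+`))
  P[1, 1] <- 0
  total <- sum(P)
  if (total == 0) return(rep(0, 7))
  edges <- 0.5 * 2^(-(7:0))  # 1/256 .. 1/2, geometric
  band <- findInterval(pmin(r, 0.5), edges, rightmost.closed = TRUE)
  band <- pmax(pmin(band, 7), 1)  # sub-lowest frequencies fold into band 1
  out <- vapply(1:7, function(b) sum(P[band == b & r > 0]), 0)
  out / total
}

#' Texture features of a segment
#'
#' Six Tamura-style statistics plus seven log-spaced radial spectral-power
#' bands ("ripples"). Patches smaller than 16 x 16 are measured on a
#' zero-padded 16 x 16 canvas. A constant patch has zero contrast and zero
#' ripple power.
#'
#' @param g integer grayscale matrix.
#' @return named numeric vector of length 13, all finite.
#' @export
texture_features <- function(g) {
  if (nrow(g) < 16 || ncol(g) < 16) {
    pad <- matrix(0, max(16, nrow(g)), max(16, ncol(g)))
    pad[seq_len(nrow(g)), seq_len(ncol(g))] <- g
    g <- pad
  }
  g <- matrix(as.numeric(g), nrow(g), ncol(g))
  coars <- tamura_coarseness(g)
  contr <- tamura_contrast(as.vector(g))
  ds <- direction_stats(g)
  # regularity: 1 - normalized spread of the four base statistics over
  # the 2 x 2 quadrants of the patch
  qh <- nrow(g) %/% 2; qw <- ncol(g) %/% 2
  quads <- list(g[1:qh, 1:qw], g[1:qh, (qw + 1):ncol(g)],
                g[(qh + 1):nrow(g), 1:qw], g[(qh + 1):nrow(g), (qw + 1):ncol(g)])
  qstats <- vapply(quads, function(q) {
    qd <- direction_stats(q)
    c(tamura_coarseness(q), tamura_contrast(as.vector(q)), qd[1], qd[2])
  }, numeric(4))
  spread <- apply(qstats, 1, sd)
  denom <- pmax(abs(rowMeans(qstats)), 1e-9)
  regularity <- max(0, 1 - mean(pmin(spread / denom, 1)))
  out <- c(coarseness = coars, contrast = contr,
           directionality = unname(ds[1]), line_likeness = unname(ds[2]),
           regularity = regularity, roughness = coars + contr,
           stats::setNames(ripple_bands(g), sprintf("ripple_%d", 1:7)))
  stopifnot(all(is.finite(out)))
  out
}

#' Extract the full 39-feature vector for a segment
#'
#' @param fig a [figure_image()].
#' @param seg a [segment()] whose bbox lies within `fig`.
#' @return named numeric vector of length 39 (see [feature_names()]).
#' @export
extract_features <- function(fig, seg) {
  b <- seg$bbox
  validate_bbox(b)
  if (b[[3]] > fig$width || b[[4]] > fig$height)
    stop("segment bbox exceeds image bounds")
  px <- crop_pixels(fig, b)
  g <- gray_pixels(px)
  pos <- c(rel_x = (b[[1]] + b[[3]]) / 2 / fig$width,
           rel_y = (b[[2]] + b[[4]]) / 2 / fig$height,
           rel_w = bbox_width(b) / fig$width,
           rel_h = bbox_height(b) / fig$height,
           abs_w = bbox_width(b), abs_h = bbox_height(b))
  hist16 <- stats::setNames(histogram_features(g), sprintf("hist_%02d", 1:16))
  cols <- c(color_r = mean(px[, , 1]), color_g = mean(px[, , 2]),
            color_b = mean(px[, , 3]))
  tex <- texture_features(g)
  n_chars <- c(n_chars = nchar(gsub("\\s", "", seg$text)))
  fv <- c(pos, hist16, cols, tex, n_chars)
  names(fv) <- FEATURE_NAMES
  fv
}

#' Feature matrix for a list of segments
#'
#' @param fig a [figure_image()].
#' @param segments list of [segment()]s.
#' @return numeric matrix, one row per segment, rownames = segment ids.
#' @export
feature_matrix <- function(fig, segments) {
  m <- t(vapply(segments, function(s) extract_features(fig, s),
                numeric(length(FEATURE_NAMES))))
  rownames(m) <- vapply(segments, function(s) s$segment_id, "")
  m
}

#' Export a labeled feature matrix as CSV
#'
#' Columns: `segment_id`, the 39 features, `is_gel`.
#'
#' @param features numeric matrix from [feature_matrix()].
#' @param is_gel logical vector aligned with the rows.
#' @param path output CSV path.
#' @export
export_features <- function(features, is_gel, path) {
  df <- data.frame(segment_id = rownames(features), features,
                   is_gel = as.logical(is_gel), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled feature CSV back
#' @param path CSV written by [export_features()].
#' @return list with `features` (matrix) and `is_gel` (logical).
#' @export
import_features <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, FEATURE_NAMES, drop = FALSE])
  rownames(m) <- df$segment_id
  list(features = m, is_gel = as.logical(df$is_gel))
}
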