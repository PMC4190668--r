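# OCR adapters. Pipelines of this kind traditionally lean on proprietary
# desktop OCR engines; here OCR is an injected adapter with the contract
#     adapter(crop) -> list(text = <string>, confidence = <0..1>)
# where `crop` is a grayscale integer matrix (the segment's pixels) with the
# segment's bbox attached as attr "bbox". The default real adapter is a
# glyph-template matcher for the bundled bitmap font; tests use a mock.

#' OCR adapter constructors
#'
#' `ocr_none()` always returns empty text; `ocr_mock()` returns canned text
#' keyed by the segment's bbox (`"x0,y0,x1,y1"`); `ocr_template()` is a
#' deterministic template matcher that recognizes text rendered with the
#' bundled bitmap font ([render_text()]) at any integer scale.
#'
#' @param map named list: `"x0,y0,x1,y1"` -> text string.
#' @return a function `(crop) -> list(text, confidence)`.
#' @export
ocr_none <- function() {
  function(crop) list(text = "", confidence = 0)
}

#' @rdname ocr_none
#' @export
ocr_mock <- function(map = list()) {
  function(crop) {
    b <- attr(crop, "bbox")
    key <- if (is.null(b)) "" else paste(as.integer(b), collapse = ",")
    txt <- map[[key]]
    if (is.null(txt)) list(text = "", confidence = 0)
    else list(text = txt, confidence = 1)
  }
}

# nearest/majority resize of a logical mask to (th x tw)
resize_mask <- function(mask, th, tw) {
  nr <- nrow(mask); nc <- ncol(mask)
  rb <- round(seq(0, nr, length.out = th + 1))
  cb <- round(seq(0, nc, length.out = tw + 1))
  out <- matrix(FALSE, th, tw)
  for (i in seq_len(th)) for (j in seq_len(tw)) {
    r1 <- min(rb[i] + 1, nr); r2 <- min(max(rb[i + 1], r1), nr)
    c1 <- min(cb[j] + 1, nc); c2 <- min(max(cb[j + 1], c1), nc)
    out[i, j] <- mean(mask[r1:r2, c1:c2]) > 0.5
  }
  out
}

# greedy 1-D clustering: sort values, start a new cluster when the gap to
# the previous value exceeds `tol`
cutree_1d <- function(x, tol) {
  o <- order(x)
  cl <- integer(length(x))
  cur <- 1L
  cl[o[1]] <- cur
  for (i in seq_along(o)[-1]) {
    if (x[o[i]] - x[o[i - 1]] > tol) cur <- cur + 1L
    cl[o[i]] <- cur
  }
  cl
}

.glyph_tight <- function() {
  lapply(.FONT5x7, function(g) {
    rr <- range(which(rowSums(g) > 0)); cc <- range(which(colSums(g) > 0))
    g[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  })
}

#' @rdname ocr_none
#' @export
ocr_template <- function() {
  tights <- .glyph_tight()
  t_ar <- vapply(tights, function(g) ncol(g) / nrow(g), 0)
  function(crop) {
    g <- crop
    if (length(dim(g)) == 3) g <- gray_pixels(g)
    rng <- range(g)
    if (diff(rng) < 40) return(list(text = "", confidence = 0))
    dark <- g < mean(rng)
    lab <- .label_components(dark, connectivity = 8L)  # glyphs touch diagonally
    k <- max(lab)
    if (k < 1) return(list(text = "", confidence = 0))
    idx <- which(lab > 0)
    l <- lab[idx]
    rows <- (idx - 1) %% nrow(g) + 1
    cols <- (idx - 1) %/% nrow(g) + 1
    comps <- lapply(seq_len(k), function(i) {
      sel <- l == i
      if (sum(sel) < 4) return(NULL)  # speckle
      r <- range(rows[sel]); cc <- range(cols[sel])
      m <- matrix(FALSE, r[2] - r[1] + 1, cc[2] - cc[1] + 1)
      m[cbind(rows[sel] - r[1] + 1, cols[sel] - cc[1] + 1)] <- TRUE
      list(x0 = cc[1], x1 = cc[2], cy = mean(r), mask = m)
    })
    comps <- Filter(Negate(is.null), comps)
    if (!length(comps)) return(list(text = "", confidence = 0))
    # group into text lines by vertical center, read top-to-bottom then
    # left-to-right within a line
    cys <- vapply(comps, function(cp) cp$cy, 0)
    hmed <- median(vapply(comps, function(cp) nrow(cp$mask), 0))
    line_of <- cutree_1d(cys, 0.8 * hmed)
    widths <- vapply(comps, function(cp) ncol(cp$mask), 0)
    cw <- median(widths)
    out <- character(0); scores <- numeric(0)
    for (ln in sort(unique(line_of))) {
      line <- comps[line_of == ln]
      line <- line[order(vapply(line, function(cp) cp$x0, 0))]
      last_x1 <- NULL
      for (cp in line) {
        ar <- ncol(cp$mask) / nrow(cp$mask)
        best <- 0; best_ch <- ""
        # sparse structures (axes, polylines, bar charts fused with their
        # axis) are not glyphs no matter what they resize to
        if (mean(cp$mask) >= 0.18) {
          for (ch in names(tights)) {
            tg <- tights[[ch]]
            asim <- min(ar, t_ar[[ch]]) / max(ar, t_ar[[ch]])
            if (asim < 0.2) next
            # ink density must agree too: a sparse axes skeleton can
            # resize into a plus sign, but its fill fraction gives it away
            fsim <- 1 - abs(mean(cp$mask) - mean(tg))
            if (fsim < 0.7) next
            rm <- resize_mask(cp$mask, nrow(tg), ncol(tg))
            sc <- mean(rm == tg) * asim * fsim
            if (sc > best) { best <- sc; best_ch <- ch }
          }
        }
        if (!is.null(last_x1) && cp$x0 - last_x1 > 0.9 * cw)
          out <- c(out, " ")
        out <- c(out, best_ch)
        scores <- c(scores, best)
        last_x1 <- cp$x1
      }
      out <- c(out, " ")
    }
    out <- out[-length(out)]
    conf <- mean(scores)
    # plausibility prior: figure text sits on a near-white (or, inverted,
    # near-black) background; mid-gray surrounds (gel strips, photos) are
    # down-weighted so solid bands are not read as dashes or dots
    med <- median(g)
    if (med > 60 && med < 240) conf <- conf * 0.5
    list(text = paste(out, collapse = ""), confidence = conf)
  }
}

#' Run OCR on a text segment
#'
#' Adapter failures are never fatal: they produce an empty string and a
#' warning, so one bad segment cannot abort a batch run.
#'
#' @param fig a [figure_image()].
#' @param seg a TEXT [segment()].
#' @param engine an OCR adapter, e.g. [ocr_template()].
#' @return the recognized string (possibly empty).
#' @export
run_ocr <- function(fig, seg, engine) {
  stopifnot(inherits(seg, "gel_segment"))
  if (seg$kind != "TEXT") stop("run_ocr requires a TEXT segment")
  crop <- gray_pixels(crop_pixels(fig, seg$bbox))
  attr(crop, "bbox") <- seg$bbox
  res <- tryCatch(engine(crop), error = function(e) {
    warning("OCR engine failed: ", conditionMessage(e))
    list(text = "", confidence = 0)
  })
  as.character(res$text)
}
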