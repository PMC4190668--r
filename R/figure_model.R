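#' Figure images
#'
#' A figure image holds an `H x W x 3` integer pixel array with intensities
#' in `[0, 255]` (top-left origin). Grayscale sources are promoted to three
#' equal channels so downstream code can assume RGB.
#'
#' @param pixels an `H x W x 3` integer array, or an `H x W` matrix
#'   (promoted to three equal channels).
#' @param image_id identifier string; defaults to `"figure"`.
#' @return an object of class `gel_figure` with fields `image_id`, `pixels`,
#'   `width`, `height`.
#' @export
figure_image <- function(pixels, image_id = "figure") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) stop("pixels must be H x W x 3 (or H x W)")
  if (d[1] < 1 || d[2] < 1) stop("image must be at least 1 x 1")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must be integers in [0, 255]")
  structure(list(image_id = as.character(image_id), pixels = pixels,
                 width = d[2], height = d[1]),
            class = "gel_figure")
}

#' @export
print.gel_figure <- function(x, ...) {
  cat(sprintf("<gel_figure '%s' %d x %d px>\n", x$image_id, x$width, x$height))
  invisible(x)
}

#' Grayscale conversion (ITU-R 601 luma)
#'
#' `round(0.299 R + 0.587 G + 0.114 B)`, the conventional luma weighting.
#'
#' @param x a `gel_figure` or an `H x W x 3` array.
#' @return integer matrix `H x W` in `[0, 255]`.
#' @export
gray_pixels <- function(x) {
  px <- if (inherits(x, "gel_figure")) x$pixels else x
  g <- round(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
  dim(g) <- dim(px)[1:2]  # keep matrix shape even for 1 x 1 images
  storage.mode(g) <- "integer"
  g
}

# crop helper: half-open 0-based box -> R 1-based index ranges
crop_pixels <- function(fig, b) {
  validate_bbox(b)
  if (b[[3]] > fig$width || b[[4]] > fig$height)
    stop("bbox exceeds image bounds")
  fig$pixels[(b[[2]] + 1):b[[4]], (b[[1]] + 1):b[[3]], , drop = FALSE]
}

#' Read a figure image from disk
#'
#' Supports PNG (8-bit gray/RGB/RGBA, non-interlaced) and PGM/PPM (ASCII
#' `P2`/`P3` and binary `P5`/`P6`). Unreadable, truncated or unsupported
#' files (e.g. JPEG/TIFF, for which no offline decoder is available) raise
#' a `gel_format_error`, which the batch pipeline counts as a skipped
#' figure rather than aborting.
#'
#' @param path path to the image file.
#' @param image_id identifier; defaults to the file stem.
#' @return a [figure_image()].
#' @export
load_figure <- function(path, image_id = NULL) {
  if (!file.exists(path)) format_error("file not found", path)
  if (is.null(image_id))
    image_id <- tools::file_path_sans_ext(basename(path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  px <- tryCatch({
    if (length(raw) >= 8 &&
        identical(as.integer(raw[1:4]), c(137L, 80L, 78L, 71L))) {
      .png_decode(raw)
    } else if (length(raw) >= 2 && raw[1] == charToRaw("P") &&
               rawToChar(raw[2]) %in% c("2", "3", "5", "6")) {
      read_pnm(raw)
    } else if (length(raw) >= 3 &&
               identical(as.integer(raw[1:3]), c(255L, 216L, 255L))) {
      format_error("JPEG decoding is not supported offline", path)
    } else if (length(raw) >= 4 &&
               (identical(as.integer(raw[1:4]), c(73L, 73L, 42L, 0L)) ||
                identical(as.integer(raw[1:4]), c(77L, 77L, 0L, 42L)))) {
      format_error("TIFF decoding is not supported offline", path)
    } else {
      format_error("unrecognized image format", path)
    }
  }, gel_format_error = function(e) stop(e),
     error = function(e) format_error(conditionMessage(e), path))
  figure_image(px, image_id)
}

# PNM (P2/P3/P5/P6) parsing from a raw vector; maxval must be <= 255
read_pnm <- function(raw) {
  magic <- rawToChar(raw[1:2])
  pos <- 3L
  n_raw <- length(raw)
  next_token <- function() {
    repeat {
      while (pos <= n_raw && rawToChar(raw[pos]) %in% c(" ", "\t", "\n", "\r"))
        pos <<- pos + 1L
      if (pos <= n_raw && rawToChar(raw[pos]) == "#") {
        while (pos <= n_raw && rawToChar(raw[pos]) != "\n") pos <<- pos + 1L
      } else break
    }
    if (pos > n_raw) format_error("truncated PNM header")
    start <- pos
    while (pos <= n_raw && !(rawToChar(raw[pos]) %in% c(" ", "\t", "\n", "\r", "#")))
      pos <<- pos + 1L
    rawToChar(raw[start:(pos - 1L)])
  }
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || w < 1 || h < 1) format_error("bad PNM dimensions")
  if (is.na(maxval) || maxval < 1 || maxval > 255)
    format_error("unsupported PNM maxval")
  ch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n_vals <- w * h * ch
  vals <- if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (n_raw - pos + 1L < n_vals) format_error("truncated PNM pixel data")
    as.integer(raw[pos:(pos + n_vals - 1L)])
  } else {
    txt <- rawToChar(raw[pos:n_raw])
    v <- suppressWarnings(as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]]))
    if (length(v) < n_vals || anyNA(v[seq_len(n_vals)]))
      format_error("truncated PNM pixel data")
    v[seq_len(n_vals)]
  }
  if (maxval != 255L) vals <- as.integer(round(vals * 255 / maxval))
  if (ch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0L, dim = c(h, w, 3))
    for (k in 1:3)
      a[, , k] <- matrix(vals[seq(k, n_vals, by = 3)], nrow = h, byrow = TRUE)
    a
  }
}

#' Write a figure image to disk
#'
#' Format chosen by extension: `.png` (8-bit RGB), `.ppm` (binary P6) or
#' `.pgm` (binary P5, written from the luma of the pixels).
#'
#' @param fig a [figure_image()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_figure <- function(fig, path) {
  stopifnot(inherits(fig, "gel_figure"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    writeBin(.png_encode(fig$pixels), path)
  } else if (ext == "ppm") {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(sprintf("P6\n%d %d\n255\n", fig$width, fig$height)), con)
    inter <- aperm(fig$pixels, c(3, 2, 1))  # channel, col, row -> row-major RGB
    writeBin(as.raw(as.vector(inter)), con)
  } else if (ext == "pgm") {
    g <- gray_pixels(fig)
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", fig$width, fig$height)), con)
    writeBin(as.raw(as.vector(t(g))), con)
  } else stop("unsupported output format: ", ext)
  invisible(path)
}

#' Segments
#'
#' A segment is a rectangular region of a figure: the unit of
#' classification. `TEXT` segments carry OCR output (possibly empty when
#' OCR failed); `GRAPHIC` segments always have empty text.
#'
#' @param segment_id identifier string, unique within a figure.
#' @param bbox a [bbox()].
#' @param kind `"TEXT"` or `"GRAPHIC"`.
#' @param text recognized text (TEXT segments only).
#' @param source one of `"SEGMENTATION"`, `"RECTANGLE_DETECTOR"`,
#'   `"ANNOTATION"`.
#' @param is_gel optional gold-standard flag (`NA` when unknown).
#' @return an object of class `gel_segment`.
#' @export
segment <- function(segment_id, bbox, kind = c("GRAPHIC", "TEXT"), text = "",
                    source = c("SEGMENTATION", "RECTANGLE_DETECTOR", "ANNOTATION"),
                    is_gel = NA) {
  kind <- match.arg(kind)
  source <- match.arg(source)
  validate_bbox(bbox)
  if (kind == "GRAPHIC" && nzchar(text))
    validation_error("text", "GRAPHIC segments must have empty text")
  structure(list(segment_id = as.character(segment_id),
                 bbox = c(x0 = bbox[[1]], y0 = bbox[[2]],
                          x1 = bbox[[3]], y1 = bbox[[4]]),
                 kind = kind, text = as.character(text), source = source,
                 is_gel = as.logical(is_gel)),
            class = "gel_segment")
}

#' @export
print.gel_segment <- function(x, ...) {
  cat(sprintf("<gel_segment '%s' %s [%d,%d,%d,%d]%s>\n", x$segment_id, x$kind,
              x$bbox[[1]], x$bbox[[2]], x$bbox[[3]], x$bbox[[4]],
              if (x$kind == "TEXT") sprintf(" \"%s\"", x$text) else ""))
  invisible(x)
}

#' Figure annotations
#'
#' Bundles the segments of one figure with optional gold gel flags and gold
#' panel groupings (member and label segment ids), as produced by the
#' synthetic generator or by manual annotation.
#'
#' @param image_id identifier of the annotated figure.
#' @param segments list of [segment()]s.
#' @param panels list of `list(members = <ids>, labels = <ids>)`.
#' @return an object of class `gel_annotation`.
#' @export
figure_annotation <- function(image_id, segments = list(), panels = list()) {
  ann <- structure(list(image_id = as.character(image_id),
                        segments = segments, panels = panels),
                   class = "gel_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  ids <- vapply(ann$segments, function(s) s$segment_id, "")
  if (anyDuplicated(ids)) validation_error("segment_id", "duplicated ids")
  for (s in ann$segments) {
    if (!inherits(s, "gel_segment")) validation_error("segments", "not a gel_segment")
    validate_bbox(s$bbox)
  }
  for (i in seq_along(ann$panels)) {
    p <- ann$panels[[i]]
    for (fld in c("members", "labels")) {
      unknown <- setdiff(p[[fld]], ids)
      if (length(unknown))
        validation_error(sprintf("panels[%d].%s", i, fld),
                         paste("unknown segment_id:", unknown[1]))
    }
    if (length(p$members) < 1)
      validation_error(sprintf("panels[%d].members", i), "needs >= 1 member")
  }
  invisible(ann)
}

#' Read / write figure annotations (JSON)
#'
#' Schema: `{image_id, segments: [{segment_id, bbox: [x0,y0,x1,y1], kind,
#' text, is_gel?}], panels: [{members: [ids], labels: [ids]}]}` with the
#' package's half-open 0-based box convention. `read_annotation()` and
#' [write_annotation()] are inverse on valid annotations.
#'
#' @param path JSON file path.
#' @return a [figure_annotation()].
#' @export
read_annotation <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$image_id)) validation_error("image_id", "missing")
  segs <- lapply(j$segments, function(s) {
    for (fld in c("segment_id", "bbox", "kind"))
      if (is.null(s[[fld]])) validation_error(fld, "missing")
    segment(s$segment_id, unlist(s$bbox),
            kind = s$kind, text = if (is.null(s$text)) "" else s$text,
            source = if (is.null(s$source)) "ANNOTATION" else s$source,
            is_gel = if (is.null(s$is_gel)) NA else s$is_gel)
  })
  panels <- lapply(j$panels, function(p)
    list(members = as.character(unlist(p$members)),
         labels = as.character(unlist(p$labels))))
  figure_annotation(j$image_id, segs, panels)
}

#' @param ann a [figure_annotation()].
#' @rdname read_annotation
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  segs <- lapply(ann$segments, function(s) {
    rec <- list(segment_id = s$segment_id,
                bbox = as.integer(s$bbox),
                kind = s$kind, text = s$text, source = s$source)
    if (!is.na(s$is_gel)) rec$is_gel <- s$is_gel
    rec
  })
  panels <- lapply(ann$panels, function(p)
    list(members = as.list(p$members), labels = as.list(p$labels)))
  jsonlite::write_json(list(image_id = ann$image_id, segments = segs,
                            panels = panels),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
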