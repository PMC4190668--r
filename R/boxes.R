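#' Bounding boxes
#'
#' Boxes are integer pixel rectangles in a 0-based, top-left-origin
#' coordinate system, half-open on both axes: a box `c(x0, y0, x1, y1)`
#' covers pixel columns `x0 .. x1-1` and rows `y0 .. y1-1`, so
#' `width = x1 - x0` and `height = y1 - y0` with no off-by-one ambiguity.
#' For geometric distance computations the box is treated as the closed
#' continuous rectangle `[x0, x1] x [y0, y1]`.
#'
#' @param x0,y0,x1,y1 box edges in pixels; `x1 > x0`, `y1 > y0`, all `>= 0`.
#' @return a named numeric vector `c(x0, y0, x1, y1)`.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' bbox_area(b)  # 100
#' @export
bbox <- function(x0, y0, x1, y1) {
  b <- c(x0 = as.numeric(x0), y0 = as.numeric(y0),
         x1 = as.numeric(x1), y1 = as.numeric(y1))
  validate_bbox(b)
  b
}

validate_bbox <- function(b) {
  if (length(b) != 4 || anyNA(b)) validation_error("bbox", "must be 4 finite numbers")
  if (any(b != floor(b))) validation_error("bbox", "coordinates must be integers")
  if (any(b < 0)) validation_error("bbox", "coordinates must be >= 0")
  if (b[[3]] <= b[[1]]) validation_error("bbox", "x1 must be > x0")
  if (b[[4]] <= b[[2]]) validation_error("bbox", "y1 must be > y0")
  invisible(b)
}

#' @rdname bbox
#' @param b,a a bounding box.
#' @export
bbox_width <- function(b) b[[3]] - b[[1]]

#' @rdname bbox
#' @export
bbox_height <- function(b) b[[4]] - b[[2]]

#' @rdname bbox
#' @export
bbox_area <- function(b) bbox_width(b) * bbox_height(b)

# axis-aligned hull of a list of boxes
bbox_hull <- function(boxes) {
  m <- do.call(rbind, boxes)
  c(x0 = min(m[, 1]), y0 = min(m[, 2]), x1 = max(m[, 3]), y1 = max(m[, 4]))
}

# half-open intersection; NULL when empty (area-zero touches do not count)
bbox_intersect <- function(a, b) {
  x0 <- max(a[[1]], b[[1]]); y0 <- max(a[[2]], b[[2]])
  x1 <- min(a[[3]], b[[3]]); y1 <- min(a[[4]], b[[4]])
  if (x1 <= x0 || y1 <= y0) return(NULL)
  c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Intersection-over-union of two boxes
#' @rdname bbox
#' @export
bbox_iou <- function(a, b) {
  i <- bbox_intersect(a, b)
  if (is.null(i)) return(0)
  ia <- bbox_area(i)
  ia / (bbox_area(a) + bbox_area(b) - ia)
}

# set difference r \ s as a list of 0..4 disjoint boxes
bbox_subtract <- function(r, s) {
  i <- bbox_intersect(r, s)
  if (is.null(i)) return(list(r))
  out <- list()
  if (i[[2]] > r[[2]])  # strip above
    out[[length(out) + 1]] <- c(r[[1]], r[[2]], r[[3]], i[[2]])
  if (i[[4]] < r[[4]])  # strip below
    out[[length(out) + 1]] <- c(r[[1]], i[[4]], r[[3]], r[[4]])
  if (i[[1]] > r[[1]])  # left strip (between i's y-range)
    out[[length(out) + 1]] <- c(r[[1]], i[[2]], i[[1]], i[[4]])
  if (i[[3]] < r[[3]])  # right strip
    out[[length(out) + 1]] <- c(i[[3]], i[[2]], r[[3]], i[[4]])
  out
}

#' Distance between two boxes
#'
#' Euclidean distance between the closest points of two boxes, 0 when the
#' boxes intersect or touch. This is the "pixels apart" metric used by the
#' 50 px panel-adjacency rule and the 30 px label-attribution rule.
#'
#' @param a,b bounding boxes.
#' @return distance in pixels (non-negative real).
#' @examples
#' segment_distance(bbox(0, 0, 10, 10), bbox(20, 0, 30, 10))   # 10
#' segment_distance(bbox(0, 0, 10, 10), bbox(13, 14, 20, 20))  # 5
#' @export
segment_distance <- function(a, b) {
  dx <- max(0, a[[1]] - b[[3]], b[[1]] - a[[3]])
  dy <- max(0, a[[2]] - b[[4]], b[[2]] - a[[4]])
  sqrt(dx * dx + dy * dy)
}

# distance from a point to the boundary of a box: distance-to-rectangle for
# outside points, distance to the nearest side for inside points
point_to_border <- function(px, py, b) {
  dx <- max(b[[1]] - px, px - b[[3]])
  dy <- max(b[[2]] - py, py - b[[4]])
  if (dx <= 0 && dy <= 0) return(-max(dx, dy))  # inside: nearest side
  sqrt(max(0, dx)^2 + max(0, dy)^2)
}

# greatest distance from any corner of box `a` to the border of `region`
max_corner_distance <- function(a, region) {
  xs <- c(a[[1]], a[[3]]); ys <- c(a[[2]], a[[4]])
  m <- 0
  for (px in xs) for (py in ys)
    m <- max(m, point_to_border(px, py, region))
  m
}
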