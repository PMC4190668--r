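# Gel panel detection: hand-coded rules. Seed groups with segments the
# high-precision operating point accepts, expand with high-recall-positive
# neighbors (at most 50 px apart, no text segment between), merge to a
# fixpoint, then attribute surrounding text labels by the 30/150 px
# edge-distance rules. The fixpoint expansion is formulated as connected
# components of the adjacency relation restricted to high-recall
# positives, which makes it order-independent.

#' Is there a text segment between two graphic segments?
#'
#' "Between" is the open corridor: the axis-aligned hull of the two boxes
#' minus the boxes themselves. True iff any TEXT segment's bbox covers a
#' positive-area part of that corridor (touching at an edge does not
#' count).
#'
#' @param a,b GRAPHIC [segment()]s (or bare bboxes).
#' @param texts list of TEXT [segment()]s.
#' @return logical.
#' @export
has_text_between <- function(a, b, texts) {
  ba <- if (inherits(a, "gel_segment")) a$bbox else a
  bb <- if (inherits(b, "gel_segment")) b$bbox else b
  hull <- bbox_hull(list(ba, bb))
  for (t in texts) {
    bt <- if (inherits(t, "gel_segment")) t$bbox else t
    r0 <- bbox_intersect(bt, hull)
    if (is.null(r0)) next
    pieces <- bbox_subtract(r0, ba)
    remains <- unlist(lapply(pieces, bbox_subtract, s = bb), recursive = FALSE)
    if (length(remains) > 0) return(TRUE)
  }
  FALSE
}

# connected components over an arbitrary symmetric relation, by union-find;
# returns list of integer index vectors, ordered by smallest member
components_of <- function(n, related) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (related(i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- split(seq_len(n), roots)
  comps <- comps[order(vapply(comps, min, 0L))]
  unname(comps)
}

#' Group gel segments into panel cores
#'
#' Builds the adjacency graph over segments the high-recall operating
#' point accepts (edge: closest-point distance `<= adjacency_px` and no
#' text segment between), takes connected components, and keeps only
#' components containing at least one high-precision-positive seed.
#'
#' @param segments list of [segment()]s (GRAPHIC segments are scored; TEXT
#'   segments act as separators).
#' @param clf a [gel_train()]ed classifier.
#' @param features feature matrix with rownames = segment ids (see
#'   [feature_matrix()]).
#' @param adjacency_px neighbor distance threshold (default 50 px).
#' @return list of character vectors of member segment ids, in
#'   deterministic order (by first member in input order).
#' @export
group_gel_segments <- function(segments, clf, features, adjacency_px = 50) {
  if (!length(segments)) return(list())
  kinds <- vapply(segments, function(s) s$kind, "")
  ids <- vapply(segments, function(s) s$segment_id, "")
  texts <- segments[kinds == "TEXT"]
  gidx <- which(kinds == "GRAPHIC")
  if (!length(gidx)) return(list())
  fv <- features[ids[gidx], , drop = FALSE]
  scores <- gel_score(clf, fv)
  hr <- scores >= clf$thresholds[["high_recall"]]
  hp <- scores >= clf$thresholds[["high_precision"]]
  cand <- gidx[hr]
  if (!length(cand)) return(list())
  boxes <- lapply(segments[cand], `[[`, "bbox")
  related <- function(i, j) {
    segment_distance(boxes[[i]], boxes[[j]]) <= adjacency_px &&
      !has_text_between(boxes[[i]], boxes[[j]], texts)
  }
  comps <- components_of(length(cand), related)
  hp_cand <- hp[hr]
  comps <- Filter(function(ix) any(hp_cand[ix]), comps)
  lapply(comps, function(ix) ids[cand[ix]])
}

#' Attribute text labels to a gel region
#'
#' A text segment belongs to the panel iff its nearest edge is at most
#' `near_px` from the region border (closest-point distance) and its
#' farthest corner is at most `far_px` from the border.
#'
#' @param region bounding box of the gel region (hull of member boxes).
#' @param texts list of TEXT [segment()]s.
#' @param near_px,far_px the 30 / 150 px attribution thresholds.
#' @return the attributed subset of `texts`.
#' @export
attribute_labels <- function(region, texts, near_px = 30, far_px = 150) {
  validate_bbox(region)
  Filter(function(t) {
    segment_distance(t$bbox, region) <= near_px &&
      max_corner_distance(t$bbox, region) <= far_px
  }, texts)
}

#' Detect gel panels in a figure
#'
#' Composes [group_gel_segments()] and [attribute_labels()]: each kept
#' group becomes a panel whose region is the axis-aligned hull of its
#' member boxes.
#'
#' @inheritParams group_gel_segments
#' @inheritParams attribute_labels
#' @param fig the [figure_image()] (used to compute features when
#'   `features` is `NULL`).
#' @return list of `gel_panel` objects: `panel_id`, `members` (segment
#'   ids), `region` (bbox), `labels` (segment ids of attributed TEXT
#'   segments).
#' @export
detect_panels <- function(fig, segments, clf, features = NULL,
                          adjacency_px = 50, near_px = 30, far_px = 150) {
  if (is.null(features)) features <- feature_matrix(fig, segments)
  groups <- group_gel_segments(segments, clf, features, adjacency_px)
  kinds <- vapply(segments, function(s) s$kind, "")
  ids <- vapply(segments, function(s) s$segment_id, "")
  texts <- segments[kinds == "TEXT"]
  lapply(seq_along(groups), function(i) {
    members <- groups[[i]]
    region <- bbox_hull(lapply(segments[match(members, ids)], `[[`, "bbox"))
    labs <- attribute_labels(region, texts, near_px, far_px)
    structure(list(panel_id = sprintf("panel_%02d", i),
                   members = members,
                   region = region,
                   labels = vapply(labs, function(t) t$segment_id, "")),
              class = "gel_panel")
  })
}

#' @export
print.gel_panel <- function(x, ...) {
  cat(sprintf("<gel_panel '%s': %d members, %d labels, region [%d,%d,%d,%d]>\n",
              x$panel_id, length(x$members), length(x$labels),
              x$region[[1]], x$region[[2]], x$region[[3]], x$region[[4]]))
  invisible(x)
}

# panels -> annotation (for JSON export via write_annotation)
panels_to_annotation <- function(image_id, segments, panels) {
  figure_annotation(image_id, segments,
                    lapply(panels, function(p)
                      list(members = p$members, labels = p$labels)))
}
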