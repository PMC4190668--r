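# Batch orchestration over a directory of figures with attrition
# accounting: figures that fail to load, yield no segments, or error in
# any stage are skipped and counted by reason, never aborting the batch.
# The summary mirrors the corpus-scale report structure: processed
# figures, detected panels per figure, labels per panel, and gene-token
# ratios overall and within gel labels.

#' Run the full pipeline over a directory of figures
#'
#' For every image (`.png`, `.ppm`, `.pgm`) in `input_dir`: load, obtain
#' segments (from a same-stem `.json` annotation sidecar when present,
#' else by [segment_figure()]), extract features, detect panels at the
#' classifier's operating points, and recognize gene tokens in attributed
#' labels and in all text segments.
#'
#' @param input_dir directory of figures (and optional annotation
#'   sidecars).
#' @param clf a trained [gel_train()] classifier (or a model JSON path).
#' @param lexicon a [read_lexicon()] object (or a lexicon file path).
#' @param rules an [exclusion_rules()] object.
#' @param config list of thresholds: `adjacency_px` (50), `near_px` (30),
#'   `far_px` (150), `seg_config` ([segmentation_config()]), `ocr`
#'   (adapter used when no sidecar annotation exists).
#' @param out_dir optional output directory for per-figure
#'   `<id>.panels.json` / `<id>.mentions.json` and `report.json`.
#' @return a `gel_report` (see [summarize_pipeline()]) with the per-figure
#'   results attached as attribute `"figures"`.
#' @export
run_pipeline <- function(input_dir, clf, lexicon, rules = exclusion_rules(),
                         config = list(), out_dir = NULL) {
  if (is.character(clf)) clf <- load_gel_classifier(clf)
  if (is.null(lexicon)) lexicon <- read_lexicon()
  if (is.character(lexicon)) lexicon <- read_lexicon(lexicon)
  cfg <- utils::modifyList(list(adjacency_px = 50, near_px = 30, far_px = 150,
                                seg_config = segmentation_config(),
                                ocr = ocr_template()),
                           config)
  files <- sort(list.files(input_dir, pattern = "\\.(png|ppm|pgm)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) stop("no figure images found in ", input_dir)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  skipped <- c(format_error = 0L, no_segments = 0L, internal_error = 0L)
  log <- list()
  for (f in files) {
    stem <- tools::file_path_sans_ext(f)
    t0 <- proc.time()[["elapsed"]]
    outcome <- tryCatch({
      fig <- load_figure(f)
      sidecar <- paste0(stem, ".json")
      segments <- if (file.exists(sidecar)) read_annotation(sidecar)$segments
                  else segment_figure(fig, cfg$seg_config, cfg$ocr)
      if (!length(segments)) {
        skipped[["no_segments"]] <- skipped[["no_segments"]] + 1L
        list(status = "skipped", reason = "no_segments")
      } else {
        features <- feature_matrix(fig, segments)
        panels <- detect_panels(fig, segments, clf, features,
                                adjacency_px = cfg$adjacency_px,
                                near_px = cfg$near_px, far_px = cfg$far_px)
        ids <- vapply(segments, function(s) s$segment_id, "")
        texts <- segments[vapply(segments, function(s) s$kind == "TEXT", TRUE)]
        label_ids <- unique(unlist(lapply(panels, `[[`, "labels")))
        label_segs <- texts[vapply(texts, function(s)
          s$segment_id %in% label_ids, TRUE)]
        mentions_all <- recognize_genes(texts, lexicon, rules)
        mentions_labels <- recognize_genes(label_segs, lexicon, rules)
        res <- list(status = "ok", image_id = fig$image_id,
                    n_segments = length(segments),
                    n_panels = length(panels),
                    n_labels = sum(vapply(panels, function(p)
                      length(p$labels), 0L)),
                    tokens_all = nrow(mentions_all),
                    tokens_in_labels = nrow(mentions_labels),
                    gene_tokens = sum(mentions_all$verdict == "MATCH"),
                    gene_tokens_in_labels =
                      sum(mentions_labels$verdict == "MATCH"),
                    panels = panels, mentions = mentions_labels)
        if (!is.null(out_dir)) {
          write_annotation(panels_to_annotation(fig$image_id, segments, panels),
                           file.path(out_dir,
                                     paste0(fig$image_id, ".panels.json")))
          jsonlite::write_json(mentions_labels,
                               file.path(out_dir,
                                         paste0(fig$image_id, ".mentions.json")),
                               auto_unbox = TRUE, digits = NA, na = "null")
        }
        res
      }
    },
    gel_format_error = function(e) {
      skipped[["format_error"]] <<- skipped[["format_error"]] + 1L
      list(status = "skipped", reason = "format_error",
           message = conditionMessage(e))
    },
    error = function(e) {
      skipped[["internal_error"]] <<- skipped[["internal_error"]] + 1L
      list(status = "skipped", reason = "internal_error",
           message = conditionMessage(e))
    })
    log[[length(log) + 1]] <- list(
      file = basename(f), status = outcome$status,
      reason = if (is.null(outcome$reason)) NA else outcome$reason,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    if (identical(outcome$status, "ok"))
      results[[length(results) + 1]] <- outcome
  }
  report <- summarize_pipeline(results, skipped)
  attr(report, "figures") <- results
  attr(report, "log") <- log
  if (!is.null(out_dir))
    write_report(report, file.path(out_dir, "report.json"))
  report
}

#' Aggregate per-figure results into a corpus report
#'
#' All ratios are exact quotients of the counts; ratios with an undefined
#' denominator (e.g. labels per panel when no panel was detected) are
#' `NA` and serialize as `null`. The aggregation is order-independent.
#'
#' @param results list of per-figure result records (status `"ok"`).
#' @param skipped named integer vector of skip counts by reason.
#' @return an object of class `gel_report`.
#' @export
summarize_pipeline <- function(results,
                               skipped = c(format_error = 0L,
                                           no_segments = 0L,
                                           internal_error = 0L)) {
  n <- length(results)
  if (n + sum(skipped) < 1) stop("no figures to summarize")
  if (n < 1) stop("no processed figures to summarize")
  tot <- function(field) sum(vapply(results, `[[`, 0, field))
  panels <- tot("n_panels"); labels <- tot("n_labels")
  tokens <- tot("tokens_all"); tokens_lab <- tot("tokens_in_labels")
  genes <- tot("gene_tokens"); genes_lab <- tot("gene_tokens_in_labels")
  structure(list(
    total_figures = n + sum(skipped),
    processed_figures = n,
    skipped = as.list(skipped),
    detected_panels = panels,
    panels_per_figure = panels / n,
    detected_labels = labels,
    labels_per_panel = if (panels > 0) labels / panels else NA_real_,
    gene_tokens = genes,
    gene_tokens_in_labels = genes_lab,
    gene_token_ratio = if (tokens > 0) genes / tokens else NA_real_,
    gene_token_ratio_in_labels =
      if (tokens_lab > 0) genes_lab / tokens_lab else NA_real_),
    class = "gel_report")
}

#' @export
print.gel_report <- function(x, ...) {
  cat("gel pipeline report\n")
  cat(sprintf("  figures: %d total, %d processed, %d skipped\n",
              x$total_figures, x$processed_figures,
              x$total_figures - x$processed_figures))
  cat(sprintf("  gel panels: %d (%.3f per figure)\n",
              x$detected_panels, x$panels_per_figure))
  cat(sprintf("  gel labels: %d (%s per panel)\n", x$detected_labels,
              if (is.na(x$labels_per_panel)) "-" else
                sprintf("%.3f", x$labels_per_panel)))
  cat(sprintf("  gene tokens: %d overall, %d in gel labels\n",
              x$gene_tokens, x$gene_tokens_in_labels))
  cat(sprintf("  gene token ratio: %s overall, %s in gel labels\n",
              if (is.na(x$gene_token_ratio)) "-" else
                sprintf("%.3f", x$gene_token_ratio),
              if (is.na(x$gene_token_ratio_in_labels)) "-" else
                sprintf("%.3f", x$gene_token_ratio_in_labels)))
  invisible(x)
}

#' Serialize a report as JSON (stable field order, full precision)
#' @param report a `gel_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
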