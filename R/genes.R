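# Gene/protein token recognition in gel-label text: tokenize, apply
# exclusion filters (length, numbers, frequent words, gel-domain words),
# then case-sensitive lexicon lookup. Capitalization is meaningful -- many
# gel-label names are acronyms (the cell line LOX vs. the gene lox), so
# lookup never folds case.

# the 22 gel-domain exclusion words (fixed default); several coincide with
# official gene symbols, which is exactly why they are excluded
DOMAIN_WORDS_22 <- c(
  "min", "hrs", "line", "type", "protein", "DNA", "RNA", "mRNA",
  "membrane", "gel", "fold", "fragment", "antigen", "enzyme", "kinase",
  "cleavage", "factor", "blot", "pro", "pre", "peptide", "cell")

#' Load a gene-symbol lexicon
#'
#' Plain text, one symbol per line, UTF-8, case preserved. Production use
#' points this at an Entrez Gene symbol export; a small fixture lexicon is
#' bundled under `inst/extdata/lexicon_fixture.txt`.
#'
#' @param path file path, or `NULL` for the bundled fixture lexicon.
#' @param source_name,version provenance strings stored on the object.
#' @return an object of class `gel_lexicon`.
#' @export
read_lexicon <- function(path = NULL, source_name = NULL, version = "0") {
  if (is.null(path)) {
    path <- system.file("extdata", "lexicon_fixture.txt", package = "gelminer")
    if (is.null(source_name)) source_name <- "fixture"
  }
  syms <- readLines(path, encoding = "UTF-8", warn = FALSE)
  syms <- unique(syms[nzchar(trimws(syms))])
  syms <- trimws(syms)
  structure(list(symbols = syms,
                 source_name = if (is.null(source_name)) basename(path)
                               else source_name,
                 version = version),
            class = "gel_lexicon")
}

#' Exclusion rules for gene-token filtering
#'
#' Tokens are excluded when they have fewer than `min_length` characters,
#' are Arabic or Roman numerals, match the frequent-word list
#' (case-insensitive; default: a bundled ~100-entry English/biomedical
#' stopword list), or match one of the 22 gel-domain words
#' (case-sensitive, fixed default).
#'
#' @param min_length minimum token length (default 3; 3-character tokens
#'   pass).
#' @param frequent_words character vector, or `NULL` for the bundled list.
#' @param domain_words character vector (default: the 22 gel-domain words).
#' @return an object of class `gel_exclusion_rules`.
#' @export
exclusion_rules <- function(min_length = 3, frequent_words = NULL,
                            domain_words = DOMAIN_WORDS_22) {
  if (is.null(frequent_words)) {
    fp <- system.file("extdata", "frequent_words.txt", package = "gelminer")
    frequent_words <- readLines(fp, encoding = "UTF-8", warn = FALSE)
  }
  frequent_words <- tolower(trimws(frequent_words))
  frequent_words <- frequent_words[nzchar(frequent_words)]
  structure(list(min_length = min_length,
                 frequent_words = frequent_words,
                 domain_words = domain_words),
            class = "gel_exclusion_rules")
}

#' Tokenize gel-label text
#'
#' Splits on any run of characters that is neither a Unicode letter nor a
#' digit; hyphens are split points too, so `"β-actin"` yields `"β"` and
#' `"actin"` (enabling the partial match of compound protein names). Empty
#' tokens are dropped, order is preserved.
#'
#' @param label_text a string (or character vector; tokens are
#'   concatenated in order).
#' @return character vector of tokens.
#' @export
tokenize <- function(label_text) {
  toks <- unlist(strsplit(label_text, "[^\\p{L}\\p{N}]+", perl = TRUE))
  toks[nzchar(toks)]
}

# strict Roman-numeral validity (case-insensitive); "VV" is not a numeral
is_roman_numeral <- function(token) {
  grepl("^(?=[IVXLCDM])M{0,4}(CM|CD|D?C{0,3})(XC|XL|L?X{0,3})(IX|IV|V?I{0,3})$",
        toupper(token), perl = TRUE)
}

is_arabic_number <- function(token) {
  grepl("^[0-9]+([.,][0-9]+)?$", token)
}

#' Test a token against the exclusion rules
#'
#' Rules fire in a fixed precedence: `TOO_SHORT` (fewer than 3
#' characters), `NUMBER` (Arabic digits or a valid Roman numeral),
#' `FREQUENT_WORD`, `DOMAIN_WORD`; the first firing reason is reported.
#'
#' @param token a non-empty token string.
#' @param rules an [exclusion_rules()] object.
#' @return `TRUE`/`FALSE`, with attribute `"reason"` (one of `TOO_SHORT`,
#'   `NUMBER`, `FREQUENT_WORD`, `DOMAIN_WORD`, or `NA` if not excluded).
#' @export
is_excluded <- function(token, rules = exclusion_rules()) {
  stopifnot(nzchar(token))
  reason <- exclusion_reason(token, rules)
  structure(!is.na(reason), reason = reason)
}

exclusion_reason <- function(token, rules) {
  if (nchar(token) < rules$min_length) return("TOO_SHORT")
  if (is_arabic_number(token) || is_roman_numeral(token)) return("NUMBER")
  if (tolower(token) %in% rules$frequent_words) return("FREQUENT_WORD")
  if (token %in% rules$domain_words) return("DOMAIN_WORD")
  NA_character_
}

#' Recognize gene/protein tokens in label segments
#'
#' Tokenizes each TEXT segment and classifies every token: `EXCLUDED` when
#' a rule fires, else `MATCH` iff the token is in the lexicon with exact
#' case, else `NO_MATCH`. Pure: identical inputs give identical output.
#'
#' @param labels list of TEXT [segment()]s (or a character vector of label
#'   strings, which are given synthetic segment ids).
#' @param lexicon a [read_lexicon()] object.
#' @param rules an [exclusion_rules()] object.
#' @return data frame of gene mentions: `token`, `matched_symbol`,
#'   `label_segment_id`, `verdict`, `reason`.
#' @export
recognize_genes <- function(labels, lexicon, rules = exclusion_rules()) {
  if (is.character(labels))
    labels <- lapply(seq_along(labels), function(i)
      segment(sprintf("label_%03d", i), bbox(0, 0, 1, 1), kind = "TEXT",
              text = labels[[i]]))
  rows <- list()
  for (s in labels) {
    stopifnot(inherits(s, "gel_segment"))
    if (s$kind != "TEXT") stop("recognize_genes requires TEXT segments")
    for (tok in tokenize(s$text)) {
      reason <- exclusion_reason(tok, rules)
      if (!is.na(reason)) {
        verdict <- "EXCLUDED"; matched <- NA_character_
      } else if (tok %in% lexicon$symbols) {
        verdict <- "MATCH"; matched <- tok
      } else {
        verdict <- "NO_MATCH"; matched <- NA_character_
      }
      rows[[length(rows) + 1]] <- data.frame(
        token = tok, matched_symbol = matched,
        label_segment_id = s$segment_id, verdict = verdict,
        reason = if (is.na(reason)) NA_character_ else reason,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(token = character(), matched_symbol = character(),
                      label_segment_id = character(), verdict = character(),
                      reason = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Gene-token ratio
#'
#' Fraction of tokens recognized as gene mentions: `MATCH` count divided
#' by the total token count.
#'
#' @param mentions data frame from [recognize_genes()].
#' @param all_tokens total token count (must be >= 1).
#' @return a fraction in `[0, 1]`.
#' @export
gene_token_ratio <- function(mentions, all_tokens) {
  if (all_tokens < 1) stop("gene_token_ratio requires at least one token")
  sum(mentions$verdict == "MATCH") / all_tokens
}
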