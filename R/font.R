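# A small built-in 5x7 bitmap font (uppercase, digits, a few symbols).
# It serves two purposes: the synthetic generator renders labels with it,
# and the template OCR adapter recognizes exactly these glyphs, so OCR
# tests are deterministic without any external engine or font file.

.FONT5x7 <- local({
  g <- list(
    "A" = c("01110","10001","10001","11111","10001","10001","10001"),
    "B" = c("11110","10001","10001","11110","10001","10001","11110"),
    "C" = c("01110","10001","10000","10000","10000","10001","01110"),
    "D" = c("11100","10010","10001","10001","10001","10010","11100"),
    "E" = c("11111","10000","10000","11110","10000","10000","11111"),
    "F" = c("11111","10000","10000","11110","10000","10000","10000"),
    "G" = c("01110","10001","10000","10111","10001","10001","01111"),
    "H" = c("10001","10001","10001","11111","10001","10001","10001"),
    "I" = c("01110","00100","00100","00100","00100","00100","01110"),
    "J" = c("00111","00010","00010","00010","00010","10010","01100"),
    "K" = c("10001","10010","10100","11000","10100","10010","10001"),
    "L" = c("10000","10000","10000","10000","10000","10000","11111"),
    "M" = c("10001","11011","10101","10101","10001","10001","10001"),
    "N" = c("10001","11001","10101","10011","10001","10001","10001"),
    "O" = c("01110","10001","10001","10001","10001","10001","01110"),
    "P" = c("11110","10001","10001","11110","10000","10000","10000"),
    "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
    "R" = c("11110","10001","10001","11110","10100","10010","10001"),
    "S" = c("01111","10000","10000","01110","00001","00001","11110"),
    "T" = c("11111","00100","00100","00100","00100","00100","00100"),
    "U" = c("10001","10001","10001","10001","10001","10001","01110"),
    "V" = c("10001","10001","10001","10001","10001","01010","00100"),
    "W" = c("10001","10001","10001","10101","10101","11011","10001"),
    "X" = c("10001","10001","01010","00100","01010","10001","10001"),
    "Y" = c("10001","10001","01010","00100","00100","00100","00100"),
    "Z" = c("11111","00001","00010","00100","01000","10000","11111"),
    "0" = c("01110","10001","10011","10101","11001","10001","01110"),
    "1" = c("00100","01100","00100","00100","00100","00100","01110"),
    "2" = c("01110","10001","00001","00010","00100","01000","11111"),
    "3" = c("11111","00010","00100","00010","00001","10001","01110"),
    "4" = c("00010","00110","01010","10010","11111","00010","00010"),
    "5" = c("11111","10000","11110","00001","00001","10001","01110"),
    "6" = c("00110","01000","10000","11110","10001","10001","01110"),
    "7" = c("11111","00001","00010","00100","01000","01000","01000"),
    "8" = c("01110","10001","10001","01110","10001","10001","01110"),
    "9" = c("01110","10001","10001","01111","00001","00010","01100"),
    "+" = c("00000","00100","00100","11111","00100","00100","00000"),
    "-" = c("00000","00000","00000","11111","00000","00000","00000"),
    "." = c("00000","00000","00000","00000","00000","01100","01100"),
    "/" = c("00001","00010","00100","00100","00100","01000","10000")
  )
  lapply(g, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]])))
    m == 1L
  })
})

#' Characters available in the bundled bitmap font
#' @return character vector of renderable glyphs (space is also accepted).
#' @export
font_chars <- function() names(.FONT5x7)

#' Render text with the bundled bitmap font
#'
#' @param text string; unsupported characters render as blank advances.
#' @param scale integer pixel scale (glyphs are 5x7 at scale 1).
#' @param fg,bg foreground/background intensities in `[0, 255]`.
#' @param pad padding in pixels around the rendered text.
#' @return integer grayscale matrix.
#' @export
render_text <- function(text, scale = 2, fg = 20, bg = 255, pad = 2) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  cw <- 5L * scale; ch <- 7L * scale; gap <- scale
  w <- if (n > 0) n * cw + (n - 1) * gap else cw
  m <- matrix(as.integer(bg), nrow = ch, ncol = w)
  x <- 0L
  for (cc in chars) {
    gl <- .FONT5x7[[cc]]
    if (!is.null(gl)) {
      big <- gl[rep(1:7, each = scale), rep(1:5, each = scale)]
      block <- m[, (x + 1):(x + cw)]
      block[big] <- as.integer(fg)
      m[, (x + 1):(x + cw)] <- block
    }
    x <- x + cw + gap
  }
  if (pad > 0) {
    out <- matrix(as.integer(bg), nrow = ch + 2 * pad, ncol = w + 2 * pad)
    out[(pad + 1):(pad + ch), (pad + 1):(pad + w)] <- m
    m <- out
  }
  m
}
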