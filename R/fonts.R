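# Character-width metrics for label measurement and PDF text. Widths come
# from the Adobe AFM files that ship with R's grDevices (Helvetica family),
# in 1/1000 em units keyed by char code.

.lv_font_cache <- new.env(parent = emptyenv())

afm_file_for <- function(face) {
  switch(face,
         plain = "hv______.afm",
         bold = "hvb_____.afm",
         oblique = "hvo_____.afm",
         stop2("unknown font face: ", face))
}

load_afm_widths <- function(face = "plain") {
  key <- paste0("w_", face)
  if (!is.null(.lv_font_cache[[key]])) return(.lv_font_cache[[key]])
  dir <- file.path(R.home("library"), "grDevices", "afm")
  f <- file.path(dir, afm_file_for(face))
  if (!file.exists(f)) f <- paste0(f, ".gz")
  widths <- rep(556L, 255L)  # fallback width for unmapped codes
  if (file.exists(f)) {
    lines <- readLines(if (endsWith(f, ".gz")) gzfile(f) else f, warn = FALSE)
    cm <- grep("^C ", lines, value = TRUE)
    code <- as.integer(sub("^C\\s+(-?\\d+)\\s*;.*$", "\\1", cm))
    wx <- as.integer(sub("^.*WX\\s+(\\d+)\\s*;.*$", "\\1", cm))
    ok <- !is.na(code) & code > 0 & code < 256 & !is.na(wx)
    widths[code[ok]] <- wx[ok]
  }
  .lv_font_cache[[key]] <- widths
  widths
}

#' Width of a text string in canvas units (mm)
#'
#' Uses Helvetica AFM metrics at the given point size; canvas units are
#' millimetres (1 pt = 25.4/72 mm).
#' @param text character vector
#' @param size_pt font size in points
#' @param face "plain", "bold" or "oblique"
#' @return numeric vector of widths in mm
#' @export
text_width_units <- function(text, size_pt, face = "plain") {
  w <- load_afm_widths(face)
  vnumeric(text, function(s) {
    if (is.na(s) || !nzchar(s)) return(0)
    codes <- utf8ToInt(s)
    codes[codes < 1 | codes > 255] <- 109L  # fall back to 'm'
    sum(w[codes]) / 1000 * size_pt * 25.4 / 72
  })
}

# text height in mm for a font size in points
text_height_units <- function(size_pt) size_pt * 25.4 / 72
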