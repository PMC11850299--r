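#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Reverse complement of a nucleotide string
#' @param s nucleotide string (case preserved as upper)
#' @return character scalar
#' @keywords internal
revcomp <- function(s) {
  chartr("ACGTUNRYSWKMBDHVacgtunryswkmbdhv",
         "TGCAANYRSWMKVHDBtgcaanyrswmkvhdb",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# vapply shorthands
vcharacter <- function(x, f, ...) vapply(x, f, character(1), ..., USE.NAMES = FALSE)
vnumeric   <- function(x, f, ...) vapply(x, f, numeric(1),   ..., USE.NAMES = FALSE)
vinteger   <- function(x, f, ...) vapply(x, f, integer(1),   ..., USE.NAMES = FALSE)
vlogical   <- function(x, f, ...) vapply(x, f, logical(1),   ..., USE.NAMES = FALSE)

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

#' Wrap a long string into fixed-width chunks
#' @keywords internal
chunk_string <- function(s, width) {
  n <- nchar(s)
  if (n == 0) return(character(0))
  starts <- seq(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
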