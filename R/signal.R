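# Genomic signal tracks for the browser mode: bedGraph parsing (bigWig via
# a converter adapter), GC content and GC skew sequence-property tracks,
# image-width-aware moving-average smoothing and mean-centring.
#
# Tracks are expanded per base over their span (phage/plasmid scale), which
# keeps smoothing and slicing simple.

new_track <- function(locus_id, span, values, kind, positions = NULL,
                      step = 1L, centred = FALSE, annotation = NULL,
                      smoothing_window = 1L, mask = NULL) {
  if (is.null(positions)) positions <- seq.int(span[1], by = step,
                                               length.out = length(values))
  structure(list(
    locus_id = locus_id, span = span, values = values, positions = positions,
    step = as.integer(step), kind = kind,
    mean_value = mean(values), value_range = range(values),
    centred = centred, annotation = annotation,
    smoothing_window = as.integer(smoothing_window), mask = mask
  ), class = "lv_track")
}

#' @export
print.lv_track <- function(x, ...) {
  cat(sprintf("<lv_track> %s on %s [%d,%d): %d points (step %d)%s\n",
              x$kind, x$locus_id, x$span[1], x$span[2], length(x$values),
              x$step, if (x$centred) ", centred" else ""))
  invisible(x)
}

#' Read a bedGraph interval file into a per-base signal track
#'
#' bedGraph rows are `chrom start end value` with 0-based half-open
#' intervals. The track is restricted to `span`; uncovered bases are 0.
#' Rows for other chromosomes are skipped with a warning; overlapping
#' intervals resolve last-wins with a warning; malformed rows error with
#' their line number.
#'
#' @param path bedGraph file
#' @param locus_id chromosome/locus to extract
#' @param span 0-based half-open `c(start, end)` window
#' @return an `lv_track` of kind "coverage"
#' @export
parse_bedgraph <- function(path, locus_id, span) {
  if (!file.exists(path)) stop2("cannot read bedGraph file: ", path)
  lines <- readLines(path, warn = FALSE)
  n_bases <- span[2] - span[1]
  if (n_bases <= 0) stop2("empty span requested")
  values <- numeric(n_bases)
  covered <- logical(n_bases)
  overlap_warned <- FALSE
  skipped <- character(0)
  any_rows <- FALSE
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt) || startsWith(txt, "#") || startsWith(txt, "track") ||
        startsWith(txt, "browser")) next
    f <- strsplit(txt, "[\t ]+")[[1]]
    if (length(f) != 4L)
      stop2(path, ": malformed bedGraph row at line ", ln,
            " (expected 4 fields, found ", length(f), ")")
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s) || is.na(e) || is.na(v) || e < s)
      stop2(path, ": malformed bedGraph row at line ", ln)
    if (f[1] != locus_id) { skipped <- union(skipped, f[1]); next }
    any_rows <- TRUE
    s <- max(s, span[1]); e <- min(e, span[2])
    if (e <= s) next
    idx <- seq.int(s - span[1] + 1L, e - span[1])
    if (!overlap_warned && any(covered[idx])) {
      warn2(path, ": overlapping bedGraph intervals; keeping the last value")
      overlap_warned <- TRUE
    }
    values[idx] <- v
    covered[idx] <- TRUE
  }
  if (length(skipped))
    warn2(path, ": skipped rows for non-matching chromosome(s): ",
          paste(skipped, collapse = ", "))
  if (!any_rows)
    warn2(path, ": no intervals for '", locus_id, "'; track is all zero")
  new_track(locus_id, span, values, kind = "coverage")
}

#' Write a signal track as bedGraph (run-length compressed)
#' @param track an `lv_track` (per-base, step 1)
#' @param path output file
#' @param digits value rounding for run-length merging
#' @export
write_bedgraph <- function(track, path, digits = 4) {
  v <- round(track$values, digits)
  r <- rle(v)
  ends <- track$span[1] + cumsum(r$lengths) * track$step
  starts <- c(track$span[1], utils::head(ends, -1))
  keep <- r$values != 0
  df <- sprintf("%s\t%d\t%d\t%s", track$locus_id, starts[keep], ends[keep],
                formatC(r$values[keep], format = "fg", digits = 8))
  writeLines(df, path)
  invisible(path)
}

#' Convert bigWig to bedGraph with an external converter, then parse
#'
#' The conversion is delegated to a `bigWigToBedGraph`-style executable
#' (`converter input output`); the parsed result follows the
#' [parse_bedgraph()] contract.
#' @inheritParams parse_bedgraph
#' @param converter converter executable (default `"bigWigToBedGraph"`)
#' @return an `lv_track`
#' @export
bigwig_to_track <- function(path, locus_id, span,
                            converter = "bigWigToBedGraph") {
  if (!nzchar(Sys.which(converter)) && !file.exists(converter))
    stop2("bigWig converter '", converter, "' not found; convert the file to ",
          "bedGraph and use parse_bedgraph() instead")
  out <- tempfile(fileext = ".bedgraph")
  on.exit(unlink(out))
  status <- suppressWarnings(system2(converter, c(shQuote(path), shQuote(out)),
                                     stdout = FALSE, stderr = FALSE))
  if (status != 0L || !file.exists(out))
    stop2("bigWig conversion failed (exit ", status, ")")
  parse_bedgraph(out, locus_id, span)
}

# windowed base counts with centred, edge-shrunk windows via cumsum
window_counts <- function(ind, window) {
  n <- length(ind)
  cs <- c(0, cumsum(ind))
  half <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi + 1L] - cs[lo]
}

#' GC content track
#'
#' Value at each position is (#G + #C) / (#non-N bases) over a centred
#' window (shrunk at the sequence edges). Windows containing only N are 0
#' and flagged in the track's mask.
#' @param sequence nucleotide string
#' @param locus_id locus identifier for the track
#' @param window odd window size >= 1 (default 1)
#' @return an `lv_track` of kind "gc_content" with values in \[0, 1\]
#' @export
gc_content_track <- function(sequence, locus_id = "seq", window = 1L) {
  stopifnot(window >= 1, window %% 2 == 1, window <= nchar(sequence))
  ch <- strsplit(toupper(sequence), "")[[1]]
  gc <- window_counts(ch %in% c("G", "C"), window)
  valid <- window_counts(ch != "N", window)
  vals <- ifelse(valid > 0, gc / pmax(valid, 1L), 0)
  new_track(locus_id, c(0L, length(ch)), vals, kind = "gc_content",
            smoothing_window = window, mask = valid == 0)
}

#' GC skew track
#'
#' Value is (G - C) / (G + C) over a centred window (shrunk at the edges);
#' windows with G + C = 0 yield 0.
#' @inheritParams gc_content_track
#' @return an `lv_track` of kind "gc_skew" with values in \[-1, 1\]
#' @export
gc_skew_track <- function(sequence, locus_id = "seq", window = 1L) {
  stopifnot(window >= 1, window %% 2 == 1, window <= nchar(sequence))
  ch <- strsplit(toupper(sequence), "")[[1]]
  g <- window_counts(ch == "G", window)
  c_ <- window_counts(ch == "C", window)
  denom <- g + c_
  vals <- ifelse(denom > 0, (g - c_) / pmax(denom, 1L), 0)
  new_track(locus_id, c(0L, length(ch)), vals, kind = "gc_skew",
            smoothing_window = window, mask = denom == 0)
}

#' Image-width-aware moving-average smoothing
#'
#' Chooses the smoothing window from the plot geometry: with a target of
#' `points_per_unit` plotted points per canvas unit, the target point count
#' is P = ceiling(plot_width_units * points_per_unit) and the window is
#' w = max(1, floor(span / P)). The track is smoothed with a centred
#' boxcar of width w (edge-shrunk) and subsampled at block centres every w
#' bases, so each retained point is the mean of one length-w block; with
#' w = 1 the track is returned unchanged.
#'
#' @param track an `lv_track` (per-base)
#' @param plot_width_units width available for the track, in canvas units
#' @param points_per_unit plotted-point density that triggers smoothing
#'   (default 2)
#' @return a smoothed `lv_track` (possibly the input, when w = 1)
#' @export
smooth_adaptive <- function(track, plot_width_units, points_per_unit = 2) {
  stopifnot(plot_width_units > 0, points_per_unit > 0)
  n <- length(track$values)
  P <- ceiling(plot_width_units * points_per_unit)
  w <- max(1L, floor(n / P))
  if (w == 1L) return(track)
  v <- track$values
  cs <- c(0, cumsum(v))
  lo_h <- w %/% 2L
  hi_h <- w - lo_h - 1L  # centred window of exactly w bases
  i <- seq_len(n)
  lo <- pmax(i - lo_h, 1L)
  hi <- pmin(i + hi_h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  idx <- seq.int(lo_h + 1L, n, by = w)
  new_track(track$locus_id, track$span, sm[idx], kind = track$kind,
            positions = track$span[1] + idx - 1L, step = w,
            centred = track$centred, annotation = track$annotation,
            smoothing_window = w)
}

#' Centre a track at its mean
#'
#' Subtracts the mean and stores the raw mean/min/max as the annotation
#' shown in the corner of the rendered track panel. Idempotent: centring an
#' already-centred track returns it unchanged.
#' @param track an `lv_track`
#' @return the centred `lv_track`
#' @export
centre_track <- function(track) {
  if (isTRUE(track$centred)) return(track)
  if (!length(track$values)) stop2("cannot centre an empty track")
  ann <- list(mean = mean(track$values), min = min(track$values),
              max = max(track$values))
  new_track(track$locus_id, track$span, track$values - ann$mean,
            kind = track$kind, positions = track$positions,
            step = track$step, centred = TRUE, annotation = ann,
            smoothing_window = track$smoothing_window, mask = track$mask)
}
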