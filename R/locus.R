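# Domain containers: locus, feature table, regions.
#
# Internal coordinates are 0-based half-open throughout; GenBank/GFF
# (1-based inclusive) are converted at the parsing boundary. Features that
# span the origin of a circular sequence are stored as a single row with
# `wraps = TRUE`, meaning the occupied span is [start, length) followed by
# [0, end).

# Label patterns that mark a protein as hypothetical / of unknown function.
DEFAULT_HYPOTHETICAL_PATTERNS <- c("hypothetical protein", "unknown function",
                                   "uncharacterized")

#' Construct an empty feature table
#' @return zero-row data.frame with the canonical feature columns
#' @keywords internal
empty_features <- function() {
  data.frame(
    feature_id  = character(0),
    type        = character(0),
    start       = integer(0),
    end         = integer(0),
    strand      = character(0),
    label       = character(0),
    protein_seq = character(0),
    group_id    = character(0),
    group_class = character(0),
    category    = character(0),
    hypothetical = logical(0),
    wraps       = logical(0),
    show_label  = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Create a locus object
#'
#' A locus is one input nucleotide sequence (a phage or plasmid genome, or a
#' region of a longer genome) displayed as one row of a comparative figure.
#'
#' @param locus_id identifier, unique within a locus set.
#' @param sequence nucleotide string (may be `NA` when only annotation is
#'   available; sequence-dependent tracks then error).
#' @param length_bp sequence length; inferred from `sequence` when missing.
#' @param circular logical, circular topology.
#' @param description free-text description.
#' @param features feature data.frame (see [empty_features()] columns).
#' @param regions data.frame with columns `start`, `end`, `wraps_origin`
#'   (0-based half-open display windows); defaults to the full sequence.
#' @return an object of class `lv_locus`
#' @export
new_locus <- function(locus_id, sequence = NA_character_, length_bp = NULL,
                      circular = FALSE, description = "",
                      features = empty_features(), regions = NULL) {
  if (is.null(length_bp)) {
    if (is.na(sequence)) stop2("locus '", locus_id, "': need sequence or length_bp")
    length_bp <- nchar(sequence)
  }
  if (!is.na(sequence) && nchar(sequence) != length_bp)
    stop2("locus '", locus_id, "': length_bp (", length_bp,
          ") does not match sequence length (", nchar(sequence), ")")
  if (length_bp < 1) stop2("locus '", locus_id, "': length_bp must be >= 1")
  if (is.null(regions) || nrow(regions) == 0) {
    regions <- data.frame(start = 0L, end = as.integer(length_bp),
                          wraps_origin = FALSE)
  }
  structure(list(
    locus_id = locus_id,
    description = description,
    length_bp = as.integer(length_bp),
    circular = isTRUE(circular),
    sequence = if (is.na(sequence)) NA_character_ else toupper(sequence),
    features = features,
    regions = regions,
    order_hint = NA_integer_,
    cluster_hint = NA_character_
  ), class = "lv_locus")
}

#' @export
print.lv_locus <- function(x, ...) {
  cat(sprintf("<lv_locus> %s: %d bp, %s, %d features (%d CDS)\n",
              x$locus_id, x$length_bp,
              if (x$circular) "circular" else "linear",
              nrow(x$features), sum(x$features$type == "CDS")))
  invisible(x)
}

#' Bundle loci into a locus set
#' @param loci list of `lv_locus`
#' @return object of class `lv_locus_set` (a named list of loci)
#' @export
locus_set <- function(loci) {
  ids <- vcharacter(loci, function(l) l$locus_id)
  if (anyDuplicated(ids)) stop2("duplicate locus ids: ",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(loci) <- ids
  structure(loci, class = "lv_locus_set")
}

#' @export
print.lv_locus_set <- function(x, ...) {
  cat(sprintf("<lv_locus_set> %d loci, %d features total\n", length(x),
              sum(vinteger(x, function(l) nrow(l$features)))))
  invisible(x)
}

#' Displayed span of a feature, in bases
#' @keywords internal
feature_span <- function(start, end, wraps, length_bp) {
  ifelse(wraps, (length_bp - start) + end, end - start)
}

#' Displayed span of a region, in bases
#' @keywords internal
region_span <- function(region, length_bp) {
  if (region$wraps_origin) (length_bp - region$start) + region$end
  else region$end - region$start
}

#' Flag hypothetical proteins by label pattern
#'
#' Case-insensitive fixed-string match of the feature label against the
#' configured patterns (default: "hypothetical protein", "unknown function",
#' "uncharacterized").
#' @param labels character vector of feature labels
#' @param patterns patterns to match
#' @return logical vector
#' @export
is_hypothetical <- function(labels, patterns = DEFAULT_HYPOTHETICAL_PATTERNS) {
  out <- rep(FALSE, length(labels))
  lab <- tolower(labels)
  for (p in tolower(patterns)) out <- out | grepl(p, lab, fixed = TRUE)
  out[is.na(labels) | labels == ""] <- TRUE
  out
}

#' Extract the nucleotide sequence of a feature (strand-aware)
#' @keywords internal
feature_nt <- function(locus, start, end, wraps, strand) {
  if (is.na(locus$sequence))
    stop2("locus '", locus$locus_id, "' has no sequence; cannot extract feature nucleotides")
  s <- if (wraps) {
    paste0(substr(locus$sequence, start + 1L, locus$length_bp),
           substr(locus$sequence, 1L, end))
  } else {
    substr(locus$sequence, start + 1L, end)
  }
  if (strand == "-") revcomp(s) else s
}

#' Conceptually translate a CDS (bacterial/archaeal code, table 11)
#'
#' The initiator codon is translated as methionine (table-11 alternative
#' starts included); a trailing stop is removed; internal stops trigger a
#' warning naming the feature but the translation is kept.
#' @param nt in-frame nucleotide string (already spliced/strand-corrected)
#' @param feature_id used in warnings
#' @return amino-acid string
#' @export
translate_cds <- function(nt, feature_id = "<cds>") {
  nt <- toupper(nt)
  extra <- nchar(nt) %% 3L
  if (extra) {
    warn2("feature '", feature_id, "': CDS length not a multiple of 3; trailing ",
          extra, " nt ignored")
    nt <- substr(nt, 1L, nchar(nt) - extra)
  }
  gc11 <- Biostrings::getGeneticCode("11")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           genetic.code = gc11,
                                           if.fuzzy.codon = "solve"))
  if (nchar(aa) && substr(aa, nchar(aa), nchar(aa)) == "*")
    aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE))
    warn2("feature '", feature_id, "': internal stop codon in conceptual translation")
  aa
}
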