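# GenBank flat-file reader/writer.
#
# No installed package parses local GenBank flat files, so this is a small
# purpose-built reader covering the subset emitted by prokaryotic annotation
# tools: LOCUS/DEFINITION headers, a FEATURES table with simple, complement()
# and origin-spanning join() locations, quoted (possibly multi-line)
# qualifiers, and an ORIGIN sequence block. Multi-record files are split on
# the terminating "//".

#' Parse a GenBank location string
#'
#' Converts 1-based inclusive spans to 0-based half-open. An origin-spanning
#' `join(a..L,1..b)` on a circular record becomes a single wrapping span.
#' Other compound joins collapse to their outer extent with a warning.
#' @param loc location string, e.g. `"complement(10..108)"`
#' @param length_bp record length
#' @param circular circular topology flag
#' @return list(start, end, strand, wraps)
#' @keywords internal
parse_gb_location <- function(loc, length_bp, circular = FALSE) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  # peel complement(...) (possibly around join)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    segs <- strsplit(inner, ",", fixed = TRUE)[[1]]
    m <- t(vapply(segs, function(s) {
      p <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
      if (length(p) == 1L) p <- c(p, p)
      p
    }, integer(2)))
    if (circular && nrow(m) == 2L && m[1, 2] == length_bp && m[2, 1] == 1L) {
      return(list(start = m[1, 1] - 1L, end = m[2, 2], strand = strand, wraps = TRUE))
    }
    warn2("compound location '", loc, "' collapsed to its outer extent")
    return(list(start = min(m[, 1]) - 1L, end = max(m[, 2]), strand = strand,
                wraps = FALSE))
  }
  p <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(p) == 1L) p <- c(p, p)
  if (anyNA(p)) stop2("unparseable location: '", loc, "'")
  list(start = p[1] - 1L, end = p[2], strand = strand, wraps = wraps)
}

# split qualifier block lines into name/value pairs; quoted values may span
# lines (translation); unquoted continuation lines are appended with a space
# except inside /translation where they are concatenated.
parse_gb_qualifiers <- function(lines) {
  quals <- list()
  cur_name <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_name)) quals[[length(quals) + 1L]] <<- list(name = cur_name, value = cur_val)
  }
  for (ln in lines) {
    txt <- sub("^\\s+", "", ln)
    if (startsWith(txt, "/")) {
      flush()
      eq <- regexpr("=", txt, fixed = TRUE)
      if (eq == -1L) { cur_name <- substring(txt, 2L); cur_val <- TRUE; next }
      cur_name <- substring(txt, 2L, eq - 1L)
      cur_val <- substring(txt, eq + 1L)
    } else if (!is.null(cur_name) && is.character(cur_val)) {
      sep <- if (cur_name %in% c("translation")) "" else " "
      cur_val <- paste(cur_val, txt, sep = sep)
    }
  }
  flush()
  out <- lapply(quals, function(q) {
    v <- q$value
    if (is.character(v)) v <- gsub('^"|"$', "", v)
    v
  })
  names(out) <- vcharacter(quals, function(q) q$name)
  out
}

#' Read loci from a GenBank flat file
#'
#' One locus per record. CDS features take their id from `/locus_tag`
#' (fallback `/protein_id`, else a generated id), label from `/product`,
#' protein sequence from `/translation` (conceptual table-11 translation
#' when absent) and functional category from `/function`. Coordinates are
#' converted to 0-based half-open; `circular` topology on the LOCUS line is
#' honoured and origin-spanning joins become wrapping features.
#'
#' @param path GenBank file (may hold multiple records)
#' @param hypothetical_patterns label patterns marking hypothetical proteins
#' @return an `lv_locus_set`
#' @export
parse_genbank <- function(path,
                          hypothetical_patterns = DEFAULT_HYPOTHETICAL_PATTERNS) {
  if (!file.exists(path)) stop2("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(TRUE, grepl("^//\\s*$", lines)[-length(lines)])))
  loci <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//\\s*$", rec)]
    if (!any(grepl("^LOCUS", rec))) next
    loci[[length(loci) + 1L]] <-
      parse_gb_record(rec, path, hypothetical_patterns)
  }
  if (!length(loci)) stop2("no GenBank records found in ", path)
  locus_set(loci)
}

parse_gb_record <- function(rec, path, hypothetical_patterns) {
  locus_line <- rec[grepl("^LOCUS", rec)][1]
  toks <- strsplit(trimws(sub("^LOCUS", "", locus_line)), "\\s+")[[1]]
  locus_id <- toks[1]
  len <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1L][1]))
  circular <- any(tolower(toks) == "circular")

  def_i <- grep("^DEFINITION", rec)
  description <- ""
  if (length(def_i)) {
    j <- def_i[1]
    def <- sub("^DEFINITION\\s*", "", rec[j])
    while (j + 1L <= length(rec) && grepl("^\\s{5,}", rec[j + 1L]) &&
           !grepl("^FEATURES|^ACCESSION|^VERSION|^KEYWORDS|^SOURCE", rec[j + 1L])) {
      j <- j + 1L
      def <- paste(def, trimws(rec[j]))
    }
    description <- sub("\\.$", "", def)
  }

  # sequence
  ori_i <- grep("^ORIGIN", rec)
  sequence <- NA_character_
  if (length(ori_i)) {
    seq_lines <- rec[seq.int(ori_i[1] + 1L, length(rec))]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(sequence)) sequence <- NA_character_
  }
  if (is.na(len) || !length(len)) {
    if (is.na(sequence)) stop2("record '", locus_id, "' in ", path,
                               ": no length on LOCUS line and no ORIGIN sequence")
    len <- nchar(sequence)
  }
  if (!is.na(sequence) && nchar(sequence) != len) {
    warn2("record '", locus_id, "': LOCUS length ", len,
          " != ORIGIN length ", nchar(sequence), "; using ORIGIN")
    len <- nchar(sequence)
  }

  loc <- new_locus(locus_id, sequence = sequence, length_bp = len,
                   circular = circular, description = description)

  # FEATURES table
  feat_i <- grep("^FEATURES", rec)
  if (length(feat_i)) {
    end_i <- if (length(ori_i)) ori_i[1] - 1L else length(rec)
    block <- rec[seq.int(feat_i[1] + 1L, end_i)]
    block <- block[!grepl("^(BASE COUNT|CONTIG)", block)]
    is_key <- grepl("^\\s{1,10}\\S", block) & !grepl("^\\s*/", trimws(block))
    # a key line has the feature key in columns ~6-20 and location from ~21
    is_key <- grepl("^\\s{2,8}[A-Za-z0-9_'-]+\\s+\\S", block)
    idx <- which(is_key)
    feats <- list()
    n_gen <- 0L
    for (k in seq_along(idx)) {
      i0 <- idx[k]
      i1 <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      key <- strsplit(trimws(block[i0]), "\\s+")[[1]][1]
      if (key %in% c("source")) next
      rest <- sub("^\\s*\\S+\\s+", "", block[i0])
      body <- if (i1 > i0) block[seq.int(i0 + 1L, i1)] else character(0)
      # location may continue on lines not starting with '/'
      while (length(body) && !grepl("^\\s*/", body[1])) {
        rest <- paste0(rest, trimws(body[1]))
        body <- body[-1L]
      }
      pos <- parse_gb_location(rest, len, circular)
      q <- parse_gb_qualifiers(body)
      type <- if (key == "CDS") "CDS" else if (key == "tRNA") "tRNA" else "other"
      fid <- q$locus_tag %||% q$protein_id %||% NA_character_
      if (is.na(fid)) { n_gen <- n_gen + 1L; fid <- sprintf("%s_f%03d", locus_id, n_gen) }
      label <- q$product %||% q$gene %||% ""
      prot <- NA_character_
      if (type == "CDS") {
        prot <- q$translation %||% NA_character_
        if (is.na(prot)) {
          nt <- feature_nt(loc, pos$start, pos$end, pos$wraps, pos$strand)
          prot <- translate_cds(nt, fid)
        } else {
          prot <- gsub("\\s", "", prot)
        }
      }
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = fid, type = type, start = pos$start, end = pos$end,
        strand = pos$strand, label = label, protein_seq = prot,
        group_id = NA_character_, group_class = NA_character_,
        category = q[["function"]] %||% NA_character_,
        hypothetical = FALSE, wraps = pos$wraps, show_label = NA,
        stringsAsFactors = FALSE)
    }
    if (length(feats)) {
      ft <- do.call(rbind, feats)
      ft$hypothetical <- ifelse(ft$type == "CDS",
                                is_hypothetical(ft$label, hypothetical_patterns),
                                FALSE)
      loc$features <- ft
    }
  }
  loc
}

#' Write a locus set as a GenBank flat file
#'
#' Writes the subset of the format the reader consumes: LOCUS/DEFINITION,
#' FEATURES with locus_tag/product/translation (and `/function` category)
#' qualifiers, ORIGIN sequence. Origin-wrapping features are emitted as
#' `join(s..L,1..e)`. Deterministic output (fixed date stamp).
#' @param loci an `lv_locus_set` or list of loci
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genbank <- function(loci, path) {
  if (inherits(loci, "lv_locus")) loci <- list(loci)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (loc in loci) {
    L <- loc$length_bp
    writeLines(sprintf("LOCUS       %-17s %10d bp    DNA     %-8s PHG 01-JAN-2000",
                       loc$locus_id, L,
                       if (loc$circular) "circular" else "linear"), con)
    if (nzchar(loc$description))
      writeLines(sprintf("DEFINITION  %s.", loc$description), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    ft <- loc$features
    if (nrow(ft)) for (i in seq_len(nrow(ft))) {
      f <- ft[i, ]
      locstr <- if (f$wraps) sprintf("join(%d..%d,1..%d)", f$start + 1L, L, f$end)
                else sprintf("%d..%d", f$start + 1L, f$end)
      if (f$strand == "-") locstr <- sprintf("complement(%s)", locstr)
      key <- if (f$type %in% c("CDS", "tRNA")) f$type else "misc_feature"
      writeLines(sprintf("     %-16s%s", key, locstr), con)
      wq <- function(name, value) {
        txt <- sprintf('/%s="%s"', name, value)
        for (chunk in wrap_qualifier(txt)) writeLines(chunk, con)
      }
      wq("locus_tag", f$feature_id)
      if (nzchar(f$label %||% "")) wq("product", f$label)
      if (!is.na(f$category)) wq("function", f$category)
      if (f$type == "CDS" && !is.na(f$protein_seq)) wq("translation", f$protein_seq)
    }
    writeLines("ORIGIN", con)
    seq <- tolower(loc$sequence)
    starts <- seq(1L, nchar(seq), by = 60L)
    for (s in starts) {
      line <- substr(seq, s, min(s + 59L, nchar(seq)))
      grp <- paste(chunk_string(line, 10L), collapse = " ")
      writeLines(sprintf("%9d %s", s, grp), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# wrap a qualifier string to the conventional 79-column layout; values with
# spaces break at word boundaries (the parser re-joins continuation lines
# with a space, except inside /translation where it concatenates)
wrap_qualifier <- function(txt, first_indent = 21L, width = 79L) {
  avail <- width - first_indent
  if (nchar(txt) <= avail) return(paste0(strrep(" ", first_indent), txt))
  if (!grepl(" ", txt)) {
    chunks <- chunk_string(txt, avail)
  } else {
    words <- strsplit(txt, " ", fixed = TRUE)[[1]]
    chunks <- character(0)
    cur <- words[1]
    for (w in words[-1]) {
      if (nchar(cur) + 1L + nchar(w) <= avail) cur <- paste(cur, w)
      else { chunks <- c(chunks, cur); cur <- w }
    }
    chunks <- c(chunks, cur)
  }
  paste0(strrep(" ", first_indent), chunks)
}
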