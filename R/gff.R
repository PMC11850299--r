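# Extended GFF (GFF3 + embedded ##FASTA) reader/writer, the dialect written
# by prokka and pharokka. The GFF3 part is parsed by rtracklayer; the FASTA
# part by Biostrings.

#' Read loci from an extended GFF file
#'
#' Expects GFF3 with the nucleotide sequence appended after a `##FASTA`
#' directive. One locus per FASTA record. CDS rows are conceptually
#' translated (table 11, initiator rule) after splicing rows that share an
#' `ID`; an origin-spanning two-part CDS on a circular sequence becomes a
#' single wrapping feature. Labels are taken from `product` (fallback
#' `Name`); functional categories from `function` (fallback `category`).
#'
#' @inheritParams parse_genbank
#' @param path extended GFF file
#' @return an `lv_locus_set`
#' @export
parse_extended_gff <- function(path,
                               hypothetical_patterns = DEFAULT_HYPOTHETICAL_PATTERNS) {
  if (!file.exists(path)) stop2("cannot read GFF file: ", path)
  lines <- readLines(path, warn = FALSE)
  fi <- grep("^##FASTA", lines)
  if (!length(fi)) stop2("no ##FASTA section in extended GFF file: ", path)
  gff_lines <- lines[seq_len(fi[1] - 1L)]
  fa_lines <- lines[seq.int(fi[1] + 1L, length(lines))]

  tf_gff <- tempfile(fileext = ".gff3")
  tf_fa <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tf_gff, tf_fa)))
  writeLines(gff_lines, tf_gff)
  writeLines(fa_lines, tf_fa)

  seqs <- Biostrings::readDNAStringSet(tf_fa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(tf_gff, format = "gff3")

  circ_ids <- character(0)
  mc <- S4Vectors::mcols(gr)
  if ("Is_circular" %in% names(mc)) {
    circ_ids <- unique(as.character(GenomicRanges::seqnames(
      gr[!is.na(mc$Is_circular) & tolower(as.character(mc$Is_circular)) == "true"])))
  }
  # also honour ##sequence-region-independent circularity hints in directives
  circ_ids <- union(circ_ids, sub("^#!\\s*circular\\s+", "",
                                  grep("^#!\\s*circular\\s+", gff_lines, value = TRUE)))

  seq_of_row <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(seq_of_row), names(seqs))
  bad <- setdiff(bad, character(0))
  if (length(bad))
    stop2("GFF features reference sequences absent from the ##FASTA section of ",
          path, ": ", paste(bad, collapse = ", "))

  loci <- lapply(names(seqs), function(sid) {
    seq <- as.character(seqs[[sid]])
    loc <- new_locus(sid, sequence = seq, circular = sid %in% circ_ids)
    rows <- which(seq_of_row == sid)
    if (!length(rows)) return(loc)
    sub <- gr[rows]
    smc <- S4Vectors::mcols(sub)
    types <- as.character(smc$type)
    keep <- !(types %in% c("region", "gene", "mRNA", "exon", "sequence_region",
                           "remark", "source"))
    sub <- sub[keep]; smc <- smc[keep, , drop = FALSE]; types <- types[keep]
    if (!length(sub)) return(loc)
    ids <- as.character(smc$ID %||% rep(NA_character_, length(sub)))
    ids[is.na(ids) | ids == ""] <- sprintf("%s_f%03d", sid,
                                           seq_len(sum(is.na(ids) | ids == "")))
    starts1 <- GenomicRanges::start(sub)  # 1-based inclusive
    ends1 <- GenomicRanges::end(sub)
    strands <- as.character(GenomicRanges::strand(sub))
    strands[!strands %in% c("+", "-")] <- "+"
    grab <- function(col) {
      if (col %in% names(smc)) as.character(smc[[col]]) else rep(NA_character_, length(sub))
    }
    labels <- grab("product")
    alt <- grab("Name")
    labels[is.na(labels) | labels == ""] <- alt[is.na(labels) | labels == ""]
    labels[is.na(labels)] <- ""
    cats <- grab("function")
    alt2 <- grab("category")
    cats[is.na(cats)] <- alt2[is.na(cats)]

    feats <- list()
    for (uid in unique(ids)) {
      j <- which(ids == uid)
      j <- j[order(starts1[j])]
      type <- if (any(types[j] == "CDS")) "CDS"
              else if (any(types[j] == "tRNA")) "tRNA" else "other"
      strand <- strands[j[1]]
      wraps <- FALSE
      if (length(j) == 2L && loc$circular &&
          ends1[j[2]] == loc$length_bp && starts1[j[1]] == 1L) {
        # two-part origin-spanning feature: [s..L] + [1..e]
        start0 <- starts1[j[2]] - 1L
        end0 <- ends1[j[1]]
        wraps <- TRUE
      } else {
        start0 <- min(starts1[j]) - 1L
        end0 <- max(ends1[j])
        if (length(j) > 1L && !all(diff(sort(c(starts1[j], ends1[j]))) >= 0))
          warn2("feature '", uid, "': multi-row location collapsed to outer extent")
      }
      prot <- NA_character_
      if (type == "CDS") {
        nt <- feature_nt(loc, start0, end0, wraps, strand)
        prot <- translate_cds(nt, uid)
      }
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = uid, type = type, start = start0, end = end0,
        strand = strand, label = labels[j[1]], protein_seq = prot,
        group_id = NA_character_, group_class = NA_character_,
        category = cats[j[1]], hypothetical = FALSE, wraps = wraps,
        show_label = NA, stringsAsFactors = FALSE)
    }
    ft <- do.call(rbind, feats)
    ft <- ft[order(ft$start), , drop = FALSE]
    rownames(ft) <- NULL
    ft$hypothetical <- ifelse(ft$type == "CDS",
                              is_hypothetical(ft$label, hypothetical_patterns),
                              FALSE)
    loc$features <- ft
    loc
  })
  locus_set(loci)
}

#' Write a locus set as extended GFF
#'
#' GFF3 rows (CDS/tRNA/misc_feature) followed by a `##FASTA` section with
#' the nucleotide sequences. Origin-wrapping features are written as two
#' rows sharing one `ID`. Circularity is recorded with `Is_circular=true`
#' on a `region` row.
#' @param loci an `lv_locus_set` or list of loci
#' @param path output file
#' @return `path`, invisibly
#' @export
write_extended_gff <- function(loci, path) {
  if (inherits(loci, "lv_locus")) loci <- list(loci)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (loc in loci)
    writeLines(sprintf("##sequence-region %s 1 %d", loc$locus_id, loc$length_bp), con)
  esc <- function(x) gsub("([,;=&\t])", "%", x)  # conservative attribute escaping
  for (loc in loci) {
    writeLines(sprintf("%s\tlociview\tregion\t1\t%d\t.\t+\t.\tID=%s_region;Is_circular=%s",
                       loc$locus_id, loc$length_bp, loc$locus_id,
                       if (loc$circular) "true" else "false"), con)
    ft <- loc$features
    if (nrow(ft)) for (i in seq_len(nrow(ft))) {
      f <- ft[i, ]
      type <- if (f$type %in% c("CDS", "tRNA")) f$type else "misc_feature"
      attrs <- sprintf("ID=%s", f$feature_id)
      if (nzchar(f$label %||% "")) attrs <- paste0(attrs, ";product=", esc(f$label))
      if (!is.na(f$category)) attrs <- paste0(attrs, ";function=", esc(f$category))
      phase <- if (type == "CDS") "0" else "."
      if (f$wraps) {
        len1 <- loc$length_bp - f$start   # first part in sequence order from start
        writeLines(sprintf("%s\tlociview\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                           loc$locus_id, type, 1L, f$end, f$strand,
                           if (type == "CDS") sprintf("%d", (3L - len1 %% 3L) %% 3L) else ".",
                           attrs), con)
        writeLines(sprintf("%s\tlociview\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                           loc$locus_id, type, f$start + 1L, loc$length_bp,
                           f$strand, phase, attrs), con)
      } else {
        writeLines(sprintf("%s\tlociview\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                           loc$locus_id, type, f$start + 1L, f$end, f$strand,
                           phase, attrs), con)
      }
    }
  }
  writeLines("##FASTA", con)
  for (loc in loci) {
    writeLines(paste0(">", loc$locus_id), con)
    writeLines(chunk_string(loc$sequence, 70L), con)
  }
  invisible(path)
}
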