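# Small hand-built inputs used across test files.

# protein of the wanted length built from the fixture codon alphabet
fake_protein <- function(len, seed = NULL) {
  aa <- c("A","D","E","F","G","H","I","K","L","N","P","Q","R","S","T","V","W","Y")
  if (!is.null(seed)) set.seed(seed)
  paste0("M", paste(sample(aa, len - 1, replace = TRUE), collapse = ""))
}

# a minimal GenBank record string with one CDS (no /translation)
gb_record_lines <- function(id, seq, cds_loc, circular = FALSE,
                            product = "terminase") {
  c(sprintf("LOCUS       %-17s %10d bp    DNA     %-8s PHG 01-JAN-2000",
            id, nchar(seq), if (circular) "circular" else "linear"),
    sprintf("DEFINITION  test record %s.", id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    sprintf("     CDS             %s", cds_loc),
    sprintf('                     /locus_tag="%s_g1"', id),
    sprintf('                     /product="%s"', product),
    "ORIGIN",
    vapply(seq(1, nchar(seq), by = 60), function(s) {
      line <- substr(tolower(seq), s, min(s + 59, nchar(seq)))
      grp <- paste(substring(line, seq(1, nchar(line), 10),
                             pmin(seq(1, nchar(line), 10) + 9, nchar(line))),
                   collapse = " ")
      sprintf("%9d %s", s, grp)
    }, character(1)),
    "//")
}

# in-frame random sequence holding one CDS at a given 0-based start
seq_with_cds <- function(total_len, cds_start0, cds_nt, seed = 42) {
  set.seed(seed)
  bg <- paste(sample(c("A", "C", "G", "T"), total_len, replace = TRUE),
              collapse = "")
  paste0(substr(bg, 1, cds_start0), cds_nt,
         substr(bg, cds_start0 + nchar(cds_nt) + 1, total_len))
}
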