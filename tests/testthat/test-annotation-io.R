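# Parsing of GenBank and extended GFF into the internal locus model, and
# the annotation-table override machinery.

make_cds_nt <- function(protein) {
  # same fixed-codon reverse translation the fixture generator uses
  gc11 <- Biostrings::getGeneticCode("11")
  cm <- vapply(unique(gc11), function(a) sort(names(gc11)[gc11 == a])[1],
               character(1))
  names(cm) <- unique(gc11)
  paste0(paste(cm[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

test_that("GenBank coordinates convert 1-based inclusive -> 0-based half-open", {
  prot <- fake_protein(32, seed = 1)
  nt <- make_cds_nt(prot)             # 99 nt, so 10..108 one-based
  expect_equal(nchar(nt), 99L)
  seq <- seq_with_cds(1000, 9, nt)
  f <- tempfile(fileext = ".gbk")
  writeLines(gb_record_lines("REC1", seq, "10..108"), f)
  loci <- parse_genbank(f)
  ft <- loci[[1]]$features
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$start, 9L)
  expect_equal(ft$end, 108L)
  expect_equal(ft$strand, "+")
  expect_equal(nchar(ft$protein_seq), 32L)   # 33 codons minus the stop
  expect_equal(ft$protein_seq, prot)
  expect_equal(ft$label, "terminase")
  expect_false(loci[[1]]$circular)
})

test_that("complement() keeps the extent and flips the strand", {
  prot <- fake_protein(32, seed = 2)
  nt <- make_cds_nt(prot)
  # place the reverse-complement on the forward strand so that the
  # complement() feature translates to prot
  seq <- seq_with_cds(1000, 9, lociview:::revcomp(nt))
  f <- tempfile(fileext = ".gbk")
  writeLines(gb_record_lines("REC2", seq, "complement(10..108)"), f)
  ft <- parse_genbank(f)[[1]]$features
  expect_equal(ft$start, 9L)
  expect_equal(ft$end, 108L)
  expect_equal(ft$strand, "-")
  expect_equal(ft$protein_seq, prot)
})

test_that("origin-spanning join on a circular record becomes one wrapping feature", {
  prot <- fake_protein(12, seed = 3)
  nt <- make_cds_nt(prot)             # 39 nt: join(91..100,1..29) on 100 bp
  expect_equal(nchar(nt), 39L)
  set.seed(7)
  tail_part <- substr(nt, 11, 39)     # first 10 nt at 91..100, rest at 1..29
  head_part <- substr(nt, 1, 10)
  bg <- paste(sample(c("A", "C", "G", "T"), 61, replace = TRUE), collapse = "")
  seq <- paste0(tail_part, bg, head_part)
  expect_equal(nchar(seq), 100L)
  f <- tempfile(fileext = ".gbk")
  writeLines(gb_record_lines("CIRC", seq, "join(91..100,1..29)", circular = TRUE), f)
  loci <- parse_genbank(f)
  expect_true(loci[[1]]$circular)
  ft <- loci[[1]]$features
  expect_equal(nrow(ft), 1L)
  expect_true(ft$wraps)
  expect_equal(ft$start, 90L)
  expect_equal(ft$end, 29L)
  # displayed span equals a brute-force count over the concatenated coords
  brute <- length(c(91:100, 1:29))
  expect_equal(lociview:::feature_span(ft$start, ft$end, ft$wraps, 100L), brute)
  expect_equal(ft$protein_seq, prot)
})

test_that("extended GFF parses coordinates, labels and feature types", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 1, n_core = 3, n_cargo_pool = 2,
                        cargo_per_locus = 1, seed = 11)
  loc <- set$loci[[1]]
  # add a tRNA and rewrite
  tr <- data.frame(feature_id = "L01_trna1", type = "tRNA", start = 5L,
                   end = 80L, strand = "+", label = "tRNA-Gly",
                   protein_seq = NA_character_, group_id = NA_character_,
                   group_class = NA_character_, category = NA_character_,
                   hypothetical = FALSE, wraps = FALSE, show_label = NA)
  loc$features <- rbind(loc$features, tr)
  p <- file.path(d, "with_trna.gff")
  write_extended_gff(loc, p)
  got <- parse_extended_gff(p)[[1]]
  expect_equal(nrow(got$features), 5L)
  expect_equal(sum(got$features$type == "CDS"), 4L)
  expect_equal(sum(got$features$type == "tRNA"), 1L)
  g <- got$features[got$features$type == "tRNA", ]
  expect_equal(g$label, "tRNA-Gly")
  expect_true(is.na(g$protein_seq))
  cds_in <- loc$features[loc$features$type == "CDS", ]
  cds_out <- got$features[got$features$type == "CDS", ]
  expect_equal(cds_out$start, cds_in$start)
  expect_equal(cds_out$end, cds_in$end)
  expect_equal(cds_out$protein_seq, cds_in$protein_seq)
})

test_that("conceptual translation applies the table-11 initiator rule to TTG", {
  # hand-checked codons: TTG(init->M) AAA(K) CGT(R) TAA(stop)
  gff <- c("##gff-version 3",
           "chr1\t.\tCDS\t1\t12\t.\t+\t0\tID=g1;product=test protein",
           "##FASTA", ">chr1", "TTGAAACGTTAAGGGCCC")
  f <- tempfile(fileext = ".gff")
  writeLines(gff, f)
  ft <- parse_extended_gff(f)[[1]]$features
  expect_equal(ft$protein_seq, "MKR")
})

test_that("missing ##FASTA section errors naming the file", {
  f <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3", "c\t.\tCDS\t1\t9\t.\t+\t0\tID=x"), f)
  expect_error(parse_extended_gff(f), "##FASTA")
  expect_error(parse_extended_gff(f), basename(f), fixed = TRUE)
})

test_that("GFF feature for a sequence absent from ##FASTA errors", {
  gff <- c("##gff-version 3",
           "chrX\t.\tCDS\t1\t9\t.\t+\t0\tID=g1",
           "##FASTA", ">chr1", "ATGAAATAA")
  f <- tempfile(fileext = ".gff")
  writeLines(gff, f)
  expect_error(parse_extended_gff(f), "chrX")
})

test_that("GenBank <-> extended GFF round trip preserves the feature sets", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 3, n_core = 5, n_cargo_pool = 4,
                        cargo_per_locus = 2, seed = 5)
  from_gb <- parse_genbank(set$genbank)
  for (lid in names(set$loci)) {
    from_gff <- parse_extended_gff(set$gff[[lid]])[[1]]
    a <- from_gb[[lid]]$features
    b <- from_gff$features
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$start, b$start)
    expect_equal(a$end, b$end)
    expect_equal(a$strand, b$strand)
    expect_equal(a$label, b$label)
    expect_equal(a$protein_seq, b$protein_seq)
    expect_equal(from_gb[[lid]]$sequence, from_gff$sequence)
    expect_equal(from_gb[[lid]]$circular, from_gff$circular)
  }
})

test_that("parsing is deterministic across repeated reads", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 2, n_core = 4, n_cargo_pool = 3,
                        cargo_per_locus = 1, seed = 9)
  expect_identical(parse_genbank(set$genbank), parse_genbank(set$genbank))
  expect_identical(parse_extended_gff(set$gff[[1]]),
                   parse_extended_gff(set$gff[[1]]))
})

test_that("biopython agrees with the GenBank writer/reader conventions", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 2, n_core = 4, n_cargo_pool = 3,
                        cargo_per_locus = 1, seed = 21)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from Bio import SeqIO",
    "recs = list(SeqIO.parse(sys.argv[1], 'genbank'))",
    "out = []",
    "for r in recs:",
    "    for f in r.features:",
    "        if f.type != 'CDS':",
    "            continue",
    "        out.append({'id': f.qualifiers['locus_tag'][0],",
    "                    'start': int(f.location.start),",
    "                    'end': int(f.location.end),",
    "                    'strand': f.location.strand,",
    "                    'prot': f.qualifiers['translation'][0]})",
    "print(json.dumps({'n': len(recs), 'feats': out}))"), script)
  res <- system2("python", c(script, set$genbank), stdout = TRUE)
  skip_if(length(res) == 0, "biopython unavailable")
  py <- jsonlite::fromJSON(paste(res, collapse = ""))
  expect_equal(py$n, 2L)
  mine <- do.call(rbind, lapply(set$loci, function(l)
    l$features[l$features$type == "CDS", ]))
  m <- match(py$feats$id, mine$feature_id)
  expect_false(anyNA(m))
  expect_equal(py$feats$start, mine$start[m])
  expect_equal(py$feats$end, mine$end[m])
  expect_equal(ifelse(py$feats$strand == 1, "+", "-"), mine$strand[m])
  expect_equal(py$feats$prot, mine$protein_seq[m])
})

test_that("annotation tables override computed values and warn on unknown ids", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 2, n_core = 3, n_cargo_pool = 2,
                        cargo_per_locus = 1, seed = 2)
  loci <- set$loci
  ftab <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tgroup_id\tgroup_class\tshow_label",
               "L01_g001\tGRP7\tconserved\t",
               "L01_g002\tGRP7\t\tTRUE",
               "ghost\tGX\t\t"), ftab)
  ltab <- tempfile(fileext = ".tsv")
  writeLines(c("locus_id\torder\tcluster\tdescription",
               "L01\t2\tK1\tfirst locus renamed",
               "L02\t1\tK2\t"), ltab)
  expect_warning(
    loci2 <- apply_overrides(loci, load_annotation_tables(ftab, ltab)),
    "ghost")
  ft <- loci2[["L01"]]$features
  expect_equal(ft$group_id[ft$feature_id == "L01_g001"], "GRP7")
  expect_equal(ft$group_class[ft$feature_id == "L01_g001"], "conserved")
  expect_equal(ft$group_id[ft$feature_id == "L01_g002"], "GRP7")
  expect_true(ft$show_label[ft$feature_id == "L01_g002"])
  expect_equal(loci2[["L01"]]$order_hint, 2L)
  expect_equal(loci2[["L02"]]$order_hint, 1L)
  expect_equal(loci2[["L01"]]$cluster_hint, "K1")
  expect_equal(loci2[["L01"]]$description, "first locus renamed")
})

test_that("malformed table rows error with their line number", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tgroup_id", "a\tX", "broken-row-without-tab"), f)
  expect_error(load_annotation_tables(feature_table = f), "line 3")
})

test_that("locus-table region specs parse 1-based inclusive windows", {
  r <- lociview:::parse_regions_spec("11:100,201:300", 1000L)
  expect_equal(r$start, c(10L, 200L))
  expect_equal(r$end, c(100L, 300L))
  expect_false(any(r$wraps_origin))
  w <- lociview:::parse_regions_spec("91:10", 100L)
  expect_true(w$wraps_origin)
  expect_equal(w$start, 90L)
  expect_equal(w$end, 10L)
})
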