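# Synthetic fixture generator: phage-like locus sets with a known
# core/cargo structure, and analytic signal tracks. Every pipeline stage is
# testable against the generator's truth tables without downloading data.

# one fixed codon per amino acid (lexicographically first of table 11),
# so reverse translation + conceptual translation round-trips exactly
codon_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc11 <- Biostrings::getGeneticCode("11")
      aas <- unique(gc11)
      cache <<- vcharacter(aas, function(a) sort(names(gc11)[gc11 == a])[1])
      names(cache) <<- aas
    }
    cache
  }
})

random_protein <- function(len) {
  aa20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
            "T","V","W","Y")
  paste0("M", paste(sample(aa20, len - 1, replace = TRUE), collapse = ""))
}

reverse_translate <- function(protein) {
  cm <- codon_map()
  paste0(paste(cm[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  ch <- strsplit(protein, "")[[1]]
  aa20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
            "T","V","W","Y")
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- hit[hit > 1]  # keep the initiator M
  ch[hit] <- sample(aa20, length(hit), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate a synthetic phage-like locus set with known ground truth
#'
#' Each locus carries every core gene family of its block (identical
#' protein sequences per family, conserved order) plus `cargo_per_locus`
#' genes drawn from the block's cargo pool, separated by random intergenic
#' spacers. With `blocks = 2` the blocks share no families, so proteome
#' similarity between blocks is zero and sequence clustering must recover
#' the blocks. The truth table records each feature's family and the class
#' expected from the realized presence fractions under the given cutoffs.
#'
#' @param dir output directory (created); GenBank (`loci.gbk`) and one
#'   extended GFF per locus (`<locus>.gff`) are written there
#' @param n_loci number of loci (>= 1)
#' @param n_core core gene families per block
#' @param n_cargo_pool cargo families per block
#' @param cargo_per_locus cargo genes per locus
#' @param gene_len_range protein length range in amino acids
#' @param seed RNG seed (fixed; same seed gives byte-identical files)
#' @param blocks 1 or 2 similarity blocks
#' @param mutation_rate per-residue substitution rate applied to each core
#'   gene copy (0 = identical copies; use small values for clustering
#'   stress tests)
#' @param hypothetical_fraction fraction of cargo genes labelled
#'   "hypothetical protein"
#' @param with_categories attach cycling PHROG-style functional categories
#'   to core genes
#' @param conserved_cutoff,variable_cutoff cutoffs used for the expected
#'   classes in the truth table
#' @return invisible list: `loci` (an `lv_locus_set`), `truth` (data.frame
#'   feature_id, locus_id, family, block, presence_fraction, class_expected),
#'   `genbank`, `gff` (paths), `block_of` (named vector)
#' @export
make_locus_set <- function(dir, n_loci = 4, n_core = 10, n_cargo_pool = 8,
                           cargo_per_locus = 2, gene_len_range = c(60, 180),
                           seed = 1, blocks = 1, mutation_rate = 0,
                           hypothetical_fraction = 0, with_categories = FALSE,
                           conserved_cutoff = 0.75, variable_cutoff = 0.25) {
  stopifnot(n_loci >= 1, n_core >= 0, blocks %in% c(1, 2),
            cargo_per_locus <= n_cargo_pool)
  if (blocks > n_loci) stop2("more blocks than loci")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  block_of <- stats::setNames(((seq_len(n_loci) - 1L) %% blocks) + 1L,
                              sprintf("L%02d", seq_len(n_loci)))
  fam_protein <- list()
  for (b in seq_len(blocks)) {
    for (k in seq_len(n_core))
      fam_protein[[sprintf("core_b%d_%02d", b, k)]] <-
        random_protein(sample(seq(gene_len_range[1], gene_len_range[2]), 1))
    for (k in seq_len(n_cargo_pool))
      fam_protein[[sprintf("cargo_b%d_%02d", b, k)]] <-
        random_protein(sample(seq(gene_len_range[1], gene_len_range[2]), 1))
  }
  cats <- names(PHROG_PALETTE)

  loci <- list()
  truth <- list()
  for (i in seq_len(n_loci)) {
    lid <- sprintf("L%02d", i)
    b <- block_of[[lid]]
    core_fams <- sprintf("core_b%d_%02d", b, seq_len(n_core))
    cargo_fams <- sort(sample(sprintf("cargo_b%d_%02d", b, seq_len(n_cargo_pool)),
                              cargo_per_locus))
    fams <- core_fams
    for (cf in cargo_fams) {
      pos <- sample(seq_len(length(fams) + 1L), 1)
      fams <- append(fams, cf, after = pos - 1L)
    }
    seq_parts <- character(0)
    feats <- list()
    pos <- 0L
    for (j in seq_along(fams)) {
      spacer <- paste(sample(c("A", "C", "G", "T"),
                             sample(20:120, 1), replace = TRUE), collapse = "")
      seq_parts <- c(seq_parts, spacer)
      pos <- pos + nchar(spacer)
      fam <- fams[j]
      prot <- fam_protein[[fam]]
      if (startsWith(fam, "core") && mutation_rate > 0)
        prot <- mutate_protein(prot, mutation_rate)
      nt <- reverse_translate(prot)
      strand <- sample(c("+", "-"), 1)
      gene_nt <- if (strand == "-") revcomp(nt) else nt
      start <- pos
      end <- pos + nchar(nt)
      seq_parts <- c(seq_parts, gene_nt)
      pos <- end
      is_cargo <- startsWith(fam, "cargo")
      hypo <- is_cargo && stats::runif(1) < hypothetical_fraction
      label <- if (hypo) "hypothetical protein"
               else sprintf("%s protein", sub("_b\\d+_", " ", fam))
      category <- if (with_categories && !is_cargo)
        cats[(j - 1L) %% length(cats) + 1L] else NA_character_
      fid <- sprintf("%s_g%03d", lid, j)
      feats[[j]] <- data.frame(
        feature_id = fid, type = "CDS", start = start, end = end,
        strand = strand, label = label, protein_seq = prot,
        group_id = NA_character_, group_class = NA_character_,
        category = category, hypothetical = hypo, wraps = FALSE,
        show_label = NA, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        feature_id = fid, locus_id = lid, family = fam, block = b,
        stringsAsFactors = FALSE)
    }
    tail_spacer <- paste(sample(c("A", "C", "G", "T"),
                                sample(20:120, 1), replace = TRUE),
                         collapse = "")
    seq_parts <- c(seq_parts, tail_spacer)
    loc <- new_locus(lid, sequence = paste(seq_parts, collapse = ""),
                     circular = TRUE,
                     description = sprintf("synthetic phage-like locus %s", lid))
    loc$features <- do.call(rbind, feats)
    loci[[i]] <- loc
  }
  loci <- locus_set(loci)
  truth <- do.call(rbind, truth)

  # expected classes from realized presence fractions per block
  present <- unique(truth[, c("locus_id", "family", "block")])
  block_size <- table(block_of)
  fam_tab <- stats::aggregate(locus_id ~ family + block, data = present,
                              FUN = length)
  fam_tab$presence_fraction <-
    fam_tab$locus_id / as.integer(block_size[as.character(fam_tab$block)])
  fam_tab$class_expected <- ifelse(
    as.integer(block_size[as.character(fam_tab$block)]) == 1, "conserved",
    ifelse(fam_tab$presence_fraction >= conserved_cutoff, "conserved",
           ifelse(fam_tab$presence_fraction <= variable_cutoff, "variable",
                  "intermediate")))
  truth <- merge(truth, fam_tab[, c("family", "block", "presence_fraction",
                                    "class_expected")],
                 by = c("family", "block"), sort = FALSE)
  truth <- truth[order(truth$feature_id), c("feature_id", "locus_id", "family",
                                            "block", "presence_fraction",
                                            "class_expected")]
  rownames(truth) <- NULL

  gbk <- file.path(dir, "loci.gbk")
  write_genbank(loci, gbk)
  gffs <- vapply(stats::setNames(nm = names(loci)), function(lid) {
    p <- file.path(dir, paste0(lid, ".gff"))
    write_extended_gff(loci[[lid]], p)
    p
  }, character(1))
  utils::write.table(truth, file.path(dir, "truth_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(loci = loci, truth = truth, genbank = gbk, gff = gffs,
                 block_of = block_of))
}

#' Generate an analytic coverage track as bedGraph
#'
#' Per-base coverage is a sum of Gaussian bumps plus non-negative noise
#' (|N(0, noise_sd)|), written as run-length-compressed bedGraph. The
#' analytic (noise-free) profile is returned as the truth.
#'
#' @param path output bedGraph path
#' @param locus_id chromosome name written in the file
#' @param locus_length sequence length in bp
#' @param peaks list of `c(center, width, height)` vectors (0-based centres)
#' @param noise_sd standard deviation of the half-normal noise
#' @param seed RNG seed
#' @return invisible list: `truth` (analytic per-base profile), `values`
#'   (noisy per-base profile), `path`
#' @export
make_signal <- function(path, locus_id, locus_length, peaks = list(),
                        noise_sd = 0, seed = 1) {
  for (p in peaks) if (p[1] < 0 || p[1] >= locus_length)
    stop2("peak centre ", p[1], " outside the locus")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  x <- seq_len(locus_length) - 1L
  truth <- numeric(locus_length)
  for (p in peaks) truth <- truth + p[3] * exp(-((x - p[1])^2) / (2 * p[2]^2))
  values <- truth + if (noise_sd > 0) abs(stats::rnorm(locus_length, 0, noise_sd)) else 0
  tr <- new_track(locus_id, c(0L, locus_length), values, kind = "coverage")
  write_bedgraph(tr, path)
  invisible(list(truth = truth, values = values, path = path))
}
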