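# Protein homology grouping. Three routes share one contract: a built-in
# greedy identity clusterer for desk-scale inputs, a precomputed group
# table, and an adapter around an external clustering executable
# (e.g. MMseqs2; the binary is never bundled).

new_group_assignment <- function(groups, representatives, method) {
  stopifnot(all(unname(representatives) %in% names(groups)))
  structure(list(groups = groups, representatives = representatives,
                 method = method), class = "lv_groups")
}

#' @export
print.lv_groups <- function(x, ...) {
  cat(sprintf("<lv_groups> %d proteins in %d groups (method: %s)\n",
              length(x$groups), length(x$representatives), x$method))
  invisible(x)
}

# identity substitution matrix over the amino-acid alphabet: match 1,
# mismatch 0. Identity is counted on exact matches over all alignment
# columns (gap columns included in the denominator).
aa_identity_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      aa <- Biostrings::AA_ALPHABET
      m <- diag(1, length(aa))
      dimnames(m) <- list(aa, aa)
      cache <<- m
    }
    cache
  }
})

#' Global-alignment identity and coverage of two proteins
#'
#' Needleman-Wunsch global alignment (match 1, mismatch 0, gap open 10,
#' gap extension 1). Identity = exact matches / alignment columns.
#' Coverage of each sequence = residue columns aligned to a residue of the
#' other sequence / sequence length.
#' @param a,b amino-acid strings
#' @return list(identity, coverage_a, coverage_b)
#' @export
alignment_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = aa_identity_matrix(),
    gapOpening = 10, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cols <- length(ap)
  matches <- sum(ap == as_ & ap != "-")
  both <- sum(ap != "-" & as_ != "-")
  list(identity = matches / cols,
       coverage_a = both / nchar(a),
       coverage_b = both / nchar(b))
}

#' Greedy protein clustering by global-alignment identity
#'
#' Desk-scale homology grouping with a deterministic greedy set-cover
#' scheme: proteins are visited by decreasing length (ties broken by
#' lexicographic id); each joins the first existing group whose
#' representative aligns with identity >= `min_identity` and bidirectional
#' coverage >= `min_coverage`, otherwise it founds a new group. Exact
#' duplicate sequences are pooled before any alignment, and pairs whose
#' length ratio already caps identity or coverage below threshold are
#' skipped, so sets with many identical proteins cluster quickly.
#'
#' @param proteins named character vector (names are feature ids) of
#'   amino-acid sequences, or a data.frame with columns `feature_id`,
#'   `protein_seq`.
#' @param min_identity minimum identity over alignment columns (default 0.35).
#' @param min_coverage minimum bidirectional coverage (default 0.7).
#' @return an `lv_groups` assignment covering every input id
#' @export
cluster_proteins <- function(proteins, min_identity = 0.35, min_coverage = 0.7) {
  if (is.data.frame(proteins)) {
    p <- proteins$protein_seq
    names(p) <- proteins$feature_id
    proteins <- p
  }
  if (!length(proteins)) stop2("no proteins to cluster")
  stopifnot(min_identity > 0, min_identity <= 1, min_coverage > 0, min_coverage <= 1)
  empty <- !nzchar(proteins) | is.na(proteins)
  if (any(empty))
    stop2("empty protein sequence for feature(s): ",
          paste(names(proteins)[empty], collapse = ", "))
  proteins <- toupper(gsub("\\*", "", proteins))

  # pool exact duplicates; the first id in (length desc, id asc) order is the
  # unique sequence's delegate
  ord <- order(-nchar(proteins), names(proteins))
  p_ord <- proteins[ord]
  first <- !duplicated(p_ord)
  uniq_seq <- p_ord[first]
  uniq_id <- names(p_ord)[first]
  seq_key <- match(p_ord, uniq_seq)          # member -> unique index

  n_u <- length(uniq_seq)
  lens <- nchar(uniq_seq)
  group_of_uniq <- integer(n_u)
  rep_idx <- integer(0)                       # unique index of each group rep
  submat <- aa_identity_matrix()
  for (i in seq_len(n_u)) {
    # candidate representatives: length ratio already caps both identity
    # (matches <= min len, columns >= max len) and bidirectional coverage
    ratio <- pmin(lens[i], lens[rep_idx]) / pmax(lens[i], lens[rep_idx])
    cands <- which(ratio >= min_coverage & ratio >= min_identity)
    assigned <- FALSE
    if (length(cands)) {
      # one batched alignment call of the query against all candidates
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(uniq_seq[rep_idx[cands]]),
        Biostrings::AAString(uniq_seq[i]), type = "global",
        substitutionMatrix = submat, gapOpening = 10, gapExtension = 1)
      cols <- Biostrings::nchar(pa)           # alignment columns (with gaps)
      ident <- Biostrings::nmatch(pa) / cols
      ind <- Biostrings::nindel(pa)
      both <- cols - unname(Biostrings::insertion(ind)[, "WidthSum"]) -
        unname(Biostrings::deletion(ind)[, "WidthSum"])
      for (k in seq_along(cands)) {           # greedy: first match wins
        g <- cands[k]
        if (ident[k] >= min_identity &&
            both[k] / lens[rep_idx[g]] >= min_coverage &&
            both[k] / lens[i] >= min_coverage) {
          group_of_uniq[i] <- g
          assigned <- TRUE
          break
        }
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      group_of_uniq[i] <- length(rep_idx)
    }
  }
  gid <- sprintf("G%04d", seq_along(rep_idx))
  groups <- gid[group_of_uniq[seq_key]]
  names(groups) <- names(p_ord)
  groups <- groups[names(proteins)]           # restore input order
  representatives <- uniq_id[rep_idx]
  names(representatives) <- gid
  new_group_assignment(groups, representatives, "builtin_greedy")
}

#' Group assignment from a predefined protein-group table
#'
#' @param group_table data.frame with columns `feature_id`, `group_id`, or a
#'   path to such a TSV.
#' @param cds_ids ids that must be covered; uncovered ids each get a
#'   singleton group with a warning. `NULL` skips the coverage check.
#' @return an `lv_groups` assignment
#' @export
groups_from_table <- function(group_table, cds_ids = NULL) {
  if (is.character(group_table))
    group_table <- read_tsv_checked(group_table, c("feature_id", "group_id"), "group")
  df <- group_table
  dup <- df$feature_id[duplicated(df$feature_id)]
  if (length(dup)) {
    conflict <- unique(df$feature_id[df$feature_id %in% dup])
    multi <- conflict[vlogical(conflict, function(id)
      length(unique(df$group_id[df$feature_id == id])) > 1L)]
    if (length(multi))
      stop2("group table maps feature(s) to more than one group: ",
            paste(multi, collapse = ", "))
    df <- df[!duplicated(df$feature_id), , drop = FALSE]
  }
  groups <- df$group_id
  names(groups) <- df$feature_id
  if (!is.null(cds_ids)) {
    missing <- setdiff(cds_ids, names(groups))
    if (length(missing)) {
      warn2("group table does not cover ", length(missing),
            " feature(s); assigning singleton groups: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
      singletons <- paste0("SG_", missing)
      names(singletons) <- missing
      groups <- c(groups, singletons)
    }
    groups <- groups[cds_ids]
  }
  representatives <- vcharacter(unique(unname(groups)), function(g)
    names(groups)[which(groups == g)[1]])
  names(representatives) <- unique(unname(groups))
  new_group_assignment(groups, representatives, "table")
}

#' Adapter for an external protein-clustering executable
#'
#' Writes the proteins as FASTA, invokes `command fasta out_tsv [args...]`
#' and parses the resulting two-column TSV (representative_id, member_id per
#' line) into a group assignment. Extra arguments are passed verbatim. No
#' partial output files are left behind on failure.
#'
#' @inheritParams cluster_proteins
#' @param command path to the executable
#' @param args extra command-line arguments, passed verbatim
#' @return an `lv_groups` assignment
#' @export
cluster_proteins_external <- function(proteins, command, args = character(0)) {
  if (is.data.frame(proteins)) {
    p <- proteins$protein_seq
    names(p) <- proteins$feature_id
    proteins <- p
  }
  if (!nzchar(Sys.which(command)) && !file.exists(command))
    stop2("external clusterer '", command, "' not found; install it or fall ",
          "back to the built-in clusterer (cluster_proteins)")
  workdir <- tempfile("lv_cluster_")
  dir.create(workdir)
  on.exit(unlink(workdir, recursive = TRUE), add = TRUE)
  fasta <- file.path(workdir, "proteins.faa")
  out_tsv <- file.path(workdir, "clusters.tsv")
  writeLines(paste0(">", names(proteins), "\n", proteins), fasta)
  status <- suppressWarnings(
    system2(command, args = c(shQuote(fasta), shQuote(out_tsv), args),
            stdout = FALSE, stderr = FALSE))
  if (status != 0L)
    stop2("external clusterer '", command, "' exited with status ", status)
  if (!file.exists(out_tsv))
    stop2("external clusterer produced no output file")
  df <- utils::read.delim(out_tsv, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("rep", "member"))
  if (!nrow(df) || anyNA(df$rep) || anyNA(df$member))
    stop2("unparseable cluster output from '", command, "'")
  unknown <- setdiff(df$member, names(proteins))
  if (length(unknown))
    stop2("cluster output names unknown protein(s): ",
          paste(utils::head(unknown, 5), collapse = ", "))
  reps <- unique(df$rep)
  gid <- sprintf("G%04d", seq_along(reps))
  groups <- gid[match(df$rep, reps)]
  names(groups) <- df$member
  missing <- setdiff(names(proteins), names(groups))
  if (length(missing))
    stop2("cluster output does not cover protein(s): ",
          paste(utils::head(missing, 5), collapse = ", "))
  groups <- groups[names(proteins)]
  representatives <- reps
  names(representatives) <- gid
  # representatives must be members; tolerate tools that emit rep ids only
  bad <- !representatives %in% names(groups)
  if (any(bad)) representatives[bad] <- vcharacter(gid[bad], function(g)
    names(groups)[which(groups == g)[1]])
  new_group_assignment(groups, representatives, "external")
}

#' Attach a group assignment to the loci's CDS features
#' @param loci an `lv_locus_set`
#' @param assignment an `lv_groups`
#' @return the modified `lv_locus_set`
#' @export
assign_groups <- function(loci, assignment) {
  for (k in seq_along(loci)) {
    ft <- loci[[k]]$features
    m <- match(ft$feature_id, names(assignment$groups))
    hit <- !is.na(m) & ft$type == "CDS" & is.na(ft$group_id)
    ft$group_id[hit] <- unname(assignment$groups[m[hit]])
    loci[[k]]$features <- ft
  }
  loci
}

#' Per-locus sets of protein group ids
#' @param loci an `lv_locus_set` with `group_id` filled on CDS features
#' @return named list of character vectors (unique group ids per locus)
#' @export
locus_group_sets <- function(loci) {
  out <- lapply(loci, function(l) {
    g <- l$features$group_id[l$features$type == "CDS"]
    sort(unique(g[!is.na(g)]))
  })
  names(out) <- names(loci)
  out
}
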