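# Pipeline orchestration: parse -> (cluster | table) -> similarity / UPGMA
# / classification -> layout -> PDF, plus the single-locus browser run.
# Every automatic decision is also written out as an annotation table, so a
# run can be reproduced (and edited) by re-feeding its own tables.

collect_input_files <- function(paths) {
  files <- character(0)
  for (p in paths) {
    if (dir.exists(p)) {
      files <- c(files, list.files(p, pattern = "\\.(gb|gbk|gbff|genbank|gff|gff3)$",
                                   full.names = TRUE))
    } else if (file.exists(p)) files <- c(files, p)
    else stop2("input not found: ", p)
  }
  if (!length(files)) stop2("no input files found")
  sort(files)
}

parse_inputs <- function(paths, hypothetical_patterns) {
  files <- collect_input_files(paths)
  loci <- list()
  for (f in files) {
    set <- if (grepl("\\.(gff|gff3)$", f))
      parse_extended_gff(f, hypothetical_patterns)
    else parse_genbank(f, hypothetical_patterns)
    loci <- c(loci, unclass(set))
  }
  locus_set(loci)
}

#' Run the comparative locus-visualization pipeline
#'
#' Parses the inputs, assigns protein homology groups (built-in clusterer,
#' or a predefined group table, or groups already present from a feature
#' table), computes the proteome similarity/distance matrices, orders and
#' clusters the loci by UPGMA, classifies groups as conserved /
#' intermediate / variable per cluster, builds the figure layout and writes
#' the PDF together with the similarity TSV, Newick dendrogram, group-class
#' TSV and the feature/locus annotation tables it used.
#'
#' @param inputs character vector of GenBank / extended-GFF files or
#'   directories
#' @param output_dir output directory (created if needed)
#' @param config an `lv_config` from [load_profile()]
#' @param feature_table,locus_table,cluster_table optional override tables
#'   (TSV paths); see [load_annotation_tables()]
#' @param no_cluster skip the built-in clusterer; group ids must then come
#'   from `cluster_table` or the feature table
#' @param prefix basename for the output files (default "lociview")
#' @param quiet suppress per-stage log messages
#' @return invisible manifest: `files` (paths of the six outputs) plus the
#'   computed objects (`loci`, `proteome`, `classes`, `layout`, `order`,
#'   `clusters`, `colors`)
#' @export
run_comparative <- function(inputs, output_dir, config = load_profile(),
                            feature_table = NULL, locus_table = NULL,
                            cluster_table = NULL, no_cluster = FALSE,
                            prefix = "lociview", quiet = FALSE) {
  log_ <- function(...) if (!quiet) message("[lociview] ", sprintf(...))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  loci <- parse_inputs(inputs, config$hypothetical_patterns)
  loci <- disambiguate_feature_ids(loci)
  n_prot <- sum(vinteger(loci, function(l) sum(l$features$type == "CDS")))
  log_("parsed %d loci, %d protein-coding features", length(loci), n_prot)

  overrides <- load_annotation_tables(feature_table, locus_table, cluster_table)
  loci <- apply_overrides(loci, overrides)

  cds <- do.call(rbind, lapply(loci, function(l)
    l$features[l$features$type == "CDS",
               c("feature_id", "protein_seq", "group_id")]))
  if (is.null(cds) || !nrow(cds)) stop2("no protein-coding features in the input")

  need <- is.na(cds$group_id)
  if (any(need)) {
    if (no_cluster)
      stop2("clustering disabled but ", sum(need),
            " feature(s) have no group id from any table")
    ga <- cluster_proteins(cds[need, ], min_identity = config$min_identity,
                           min_coverage = config$min_coverage)
    loci <- assign_groups(loci, ga)
    log_("clustered %d proteins into %d groups", sum(need),
         length(ga$representatives))
  } else log_("protein groups taken from tables; clustering skipped")

  group_sets <- locus_group_sets(loci)
  pm <- proteome_analysis(group_sets, method = config$similarity,
                          max_distance = config$cluster_cut)

  # manual overrides: locus-table order and clusters win over the dendrogram
  order_hints <- vinteger(loci, function(l) l$order_hint %||% NA_integer_)
  final_order <- if (!all(is.na(order_hints))) {
    if (anyNA(order_hints))
      stop2("locus table must give an order for every locus (or none)")
    names(loci)[order(order_hints)]
  } else pm$leaf_order
  cluster_hints <- vcharacter(loci, function(l) l$cluster_hint %||% NA_character_)
  clusters <- if (!all(is.na(cluster_hints))) {
    if (anyNA(cluster_hints))
      stop2("locus table must give a cluster for every locus (or none)")
    stats::setNames(cluster_hints, names(loci))
  } else pm$clusters
  log_("%d sequence clusters; row order %s", length(unique(clusters)),
       paste(final_order, collapse = ", "))

  classes <- classify_protein_groups(clusters, group_sets,
                                     conserved_cutoff = config$conserved_cutoff,
                                     variable_cutoff = config$variable_cutoff)

  # attach per-feature classes (feature-table overrides already present win)
  for (k in seq_along(loci)) {
    ft <- loci[[k]]$features
    cl <- clusters[[loci[[k]]$locus_id]]
    sub <- classes[classes$cluster == cl, ]
    m <- match(ft$group_id, sub$group_id)
    fill <- is.na(ft$group_class) & !is.na(m)
    ft$group_class[fill] <- sub$class[m[fill]]
    loci[[k]]$features <- ft
  }

  all_cls <- unlist(lapply(loci, function(l) l$features$group_class))
  all_gid <- unlist(lapply(loci, function(l) l$features$group_id))
  keep <- !is.na(all_gid) & !is.na(all_cls)
  cls_vec <- stats::setNames(all_cls[keep], all_gid[keep])
  cls_vec <- cls_vec[!duplicated(names(cls_vec))]
  colors <- assign_group_colors(
    cls_vec, highlight = config$highlight, seed = config$palette_seed,
    conserved_color = config$conserved_color,
    color_intermediate = config$color_intermediate)

  loci_ordered <- locus_set(loci[final_order])
  layout <- build_layout(loci_ordered, config)
  dropped <- sum(vinteger(layout$rows, function(r)
    if (is.null(r$labels)) 0L else sum(!r$labels$placed)))
  log_("layout: %d rows, %d connectors, %d dropped labels",
       length(layout$rows), nrow(layout$connectors), dropped)

  paths <- list(
    pdf = file.path(output_dir, paste0(prefix, ".pdf")),
    similarity = file.path(output_dir, paste0(prefix, "_similarity.tsv")),
    newick = file.path(output_dir, paste0(prefix, ".nwk")),
    classes = file.path(output_dir, paste0(prefix, "_classes.tsv")),
    feature_table = file.path(output_dir, paste0(prefix, "_features.tsv")),
    locus_table = file.path(output_dir, paste0(prefix, "_loci.tsv")))
  render_pdf(layout, colors, paths$pdf)
  write_similarity_tsv(pm, paths$similarity, paths$newick)
  write_class_tsv(classes, paths$classes)
  write_annotation_tables(loci_ordered, paths$feature_table, paths$locus_table,
                          order = final_order, clusters = clusters)
  log_("wrote %s", paths$pdf)
  invisible(list(files = paths, loci = loci_ordered, proteome = pm,
                 classes = classes, layout = layout, order = final_order,
                 clusters = clusters, colors = colors))
}

#' Run the genome-browser pipeline for a single locus
#'
#' @param input one GenBank or extended-GFF file
#' @param output_pdf output PDF path
#' @param bedgraphs character vector of bedGraph files (panels appear in
#'   this order below the property tracks)
#' @param window optional `c(start, end)` window, 1-based inclusive
#' @param record locus id to select from a multi-record input
#' @param gc draw the GC content / GC skew tracks (default TRUE)
#' @param config an `lv_config`
#' @param quiet suppress log messages
#' @return invisible manifest (`layout`, `tracks`, `pdf`)
#' @export
run_browser <- function(input, output_pdf, bedgraphs = character(0),
                        window = NULL, record = NULL, gc = TRUE,
                        config = load_profile(), quiet = FALSE) {
  log_ <- function(...) if (!quiet) message("[lociview] ", sprintf(...))
  loci <- parse_inputs(input, config$hypothetical_patterns)
  if (length(loci) > 1) {
    if (is.null(record))
      stop2("input has ", length(loci), " records; select one with 'record'")
    if (!record %in% names(loci)) stop2("record '", record, "' not in input")
    locus <- loci[[record]]
  } else locus <- loci[[1]]
  if (!is.null(window)) {
    if (window[1] < 1 || window[2] > locus$length_bp || window[1] > window[2])
      stop2("window out of range for '", locus$locus_id, "'")
    locus$regions <- data.frame(start = window[1] - 1L, end = window[2],
                                wraps_origin = FALSE)
  }
  span <- c(locus$regions$start[1], locus$regions$end[1])
  tracks <- lapply(bedgraphs, function(p) parse_bedgraph(p, locus$locus_id, span))
  names(tracks) <- vcharacter(bedgraphs, function(p)
    tools::file_path_sans_ext(basename(p)))
  log_("browser: %s, %d signal track(s)", locus$locus_id, length(tracks))
  layout <- browser_panel(locus, tracks, config, gc = gc)
  colors <- character(0)
  cls <- locus$features$group_class
  gid <- locus$features$group_id
  keep <- !is.na(cls) & !is.na(gid)
  if (any(keep))
    colors <- assign_group_colors(
      stats::setNames(cls[keep], gid[keep])[!duplicated(gid[keep])],
      highlight = config$highlight, seed = config$palette_seed,
      conserved_color = config$conserved_color,
      color_intermediate = config$color_intermediate)
  render_pdf(layout, colors, output_pdf)
  log_("wrote %s", output_pdf)
  invisible(list(layout = layout, tracks = tracks, pdf = output_pdf))
}
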