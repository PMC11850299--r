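# Tab-separated annotation tables: manual overrides for feature properties
# (group id/class, label, category, label visibility), locus properties
# (row order, cluster, description, display regions) and predefined protein
# groups. Table values take precedence over computed values.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop2("cannot read ", what, " table: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) < 1L) stop2(what, " table is empty: ", path)
  bad <- which(nf != nf[1])
  if (length(bad))
    stop2(what, " table ", path, ": malformed row at line ", bad[1] + 0L,
          " (expected ", nf[1], " fields, found ", nf[bad[1]], ")")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop2(what, " table ", path, ": missing required column(s): ",
          paste(miss, collapse = ", "))
  df
}

#' Load optional annotation override tables
#'
#' All tables are tab-separated with a header row.
#' * feature table: `feature_id` plus any of `locus_id`, `group_id`,
#'   `group_class`, `label`, `category`, `show_label`.
#' * locus table: `locus_id` plus any of `order`, `cluster`, `description`,
#'   `regions` (comma-separated `start:end`, 1-based inclusive; `start > end`
#'   denotes an origin-wrapping window).
#' * group table: `feature_id`, `group_id`.
#'
#' @param feature_table,locus_table,group_table file paths or `NULL`
#' @return an `lv_overrides` object (list of data.frames)
#' @export
load_annotation_tables <- function(feature_table = NULL, locus_table = NULL,
                                   group_table = NULL) {
  out <- list(features = NULL, loci = NULL, groups = NULL)
  if (!is.null(feature_table)) {
    df <- read_tsv_checked(feature_table, "feature_id", "feature")
    if ("group_class" %in% names(df)) {
      bad <- setdiff(stats::na.omit(unique(df$group_class[df$group_class != ""])),
                     c("conserved", "intermediate", "variable"))
      if (length(bad)) stop2("feature table: invalid group_class value(s): ",
                             paste(bad, collapse = ", "))
    }
    out$features <- df
  }
  if (!is.null(locus_table)) {
    out$loci <- read_tsv_checked(locus_table, "locus_id", "locus")
  }
  if (!is.null(group_table)) {
    out$groups <- read_tsv_checked(group_table, c("feature_id", "group_id"), "group")
  }
  structure(out, class = "lv_overrides")
}

# "a:b,c:d" (1-based inclusive) -> regions data.frame; a > b wraps the origin
parse_regions_spec <- function(spec, length_bp) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    ab <- suppressWarnings(as.integer(strsplit(trimws(p), ":", fixed = TRUE)[[1]]))
    if (length(ab) != 2L || anyNA(ab)) stop2("malformed region spec: '", p, "'")
    if (ab[1] <= ab[2]) data.frame(start = ab[1] - 1L, end = ab[2], wraps_origin = FALSE)
    else data.frame(start = ab[1] - 1L, end = ab[2], wraps_origin = TRUE)
  })
  do.call(rbind, rows)
}

format_regions_spec <- function(regions) {
  paste(sprintf("%d:%d", regions$start + 1L, regions$end), collapse = ",")
}

#' Apply annotation-table overrides to parsed loci
#'
#' Table values win over parsed/computed values. Unknown feature or locus
#' ids produce a warning listing them. The group table only sets
#' `group_id`s (used to skip clustering for those features).
#'
#' @param loci an `lv_locus_set`
#' @param overrides an `lv_overrides` from [load_annotation_tables()]
#' @return the modified `lv_locus_set`
#' @export
apply_overrides <- function(loci, overrides) {
  stopifnot(inherits(overrides, "lv_overrides"))
  all_fids <- unlist(lapply(loci, function(l) l$features$feature_id))

  if (!is.null(overrides$features)) {
    df <- overrides$features
    unknown <- setdiff(df$feature_id, all_fids)
    if (length(unknown))
      warn2("feature table: unknown feature id(s): ", paste(unknown, collapse = ", "))
    for (k in seq_along(loci)) {
      ft <- loci[[k]]$features
      m <- match(ft$feature_id, df$feature_id)
      hit <- !is.na(m)
      if (!any(hit)) next
      set_chr <- function(col, target) {
        if (col %in% names(df)) {
          v <- df[[col]][m[hit]]
          keep <- !is.na(v) & v != ""
          ft[[target]][hit][keep] <<- v[keep]
        }
      }
      set_chr("group_id", "group_id")
      set_chr("group_class", "group_class")
      set_chr("label", "label")
      set_chr("category", "category")
      if ("show_label" %in% names(df)) {
        v <- df$show_label[m[hit]]
        keep <- !is.na(v) & v != ""
        ft$show_label[hit][keep] <- toupper(v[keep]) %in% c("TRUE", "T", "1", "YES")
      }
      loci[[k]]$features <- ft
    }
  }

  if (!is.null(overrides$loci)) {
    df <- overrides$loci
    unknown <- setdiff(df$locus_id, names(loci))
    if (length(unknown))
      warn2("locus table: unknown locus id(s): ", paste(unknown, collapse = ", "))
    for (k in seq_along(loci)) {
      i <- match(loci[[k]]$locus_id, df$locus_id)
      if (is.na(i)) next
      if ("order" %in% names(df) && !is.na(df$order[i]) && df$order[i] != "")
        loci[[k]]$order_hint <- as.integer(df$order[i])
      if ("cluster" %in% names(df) && !is.na(df$cluster[i]) && df$cluster[i] != "")
        loci[[k]]$cluster_hint <- df$cluster[i]
      if ("description" %in% names(df) && !is.na(df$description[i]) && df$description[i] != "")
        loci[[k]]$description <- df$description[i]
      if ("regions" %in% names(df) && !is.na(df$regions[i]) && df$regions[i] != "")
        loci[[k]]$regions <- parse_regions_spec(df$regions[i], loci[[k]]$length_bp)
    }
  }

  if (!is.null(overrides$groups)) {
    ga <- groups_from_table(overrides$groups, cds_ids = NULL)
    for (k in seq_along(loci)) {
      ft <- loci[[k]]$features
      m <- match(ft$feature_id, names(ga$groups))
      hit <- !is.na(m)
      ft$group_id[hit] <- unname(ga$groups[m[hit]])
      loci[[k]]$features <- ft
    }
  }
  loci
}

#' Make feature ids globally unique across a locus set
#'
#' Group tables are keyed globally, so colliding feature ids in different
#' loci are disambiguated by prefixing the locus id.
#' @param loci an `lv_locus_set`
#' @return the modified `lv_locus_set`
#' @export
disambiguate_feature_ids <- function(loci) {
  ids <- unlist(lapply(loci, function(l) l$features$feature_id))
  dup <- unique(ids[duplicated(ids)])
  if (!length(dup)) return(loci)
  for (k in seq_along(loci)) {
    ft <- loci[[k]]$features
    hit <- ft$feature_id %in% dup
    ft$feature_id[hit] <- paste0(loci[[k]]$locus_id, "_", ft$feature_id[hit])
    loci[[k]]$features <- ft
  }
  loci
}

#' Write the feature and locus annotation tables for a locus set
#'
#' Emitting the pipeline's decisions as tables makes every automatic choice
#' inspectable and re-usable as an override input.
#' @param loci an `lv_locus_set` (after grouping/classification)
#' @param feature_path,locus_path output TSV paths
#' @param order final row order (locus ids); defaults to list order
#' @param clusters named cluster labels per locus id (optional)
#' @return invisible list of the two paths
#' @export
write_annotation_tables <- function(loci, feature_path, locus_path,
                                    order = names(loci), clusters = NULL) {
  feats <- do.call(rbind, lapply(loci, function(l) {
    ft <- l$features
    if (!nrow(ft)) return(NULL)
    data.frame(feature_id = ft$feature_id, locus_id = l$locus_id,
               group_id = ft$group_id %val% "", group_class = ft$group_class %val% "",
               label = ft$label, category = ft$category %val% "",
               show_label = ifelse(is.na(ft$show_label), "",
                                   ifelse(ft$show_label, "TRUE", "FALSE")),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(feats, feature_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ord <- match(names(loci), order)
  ldf <- data.frame(
    locus_id = names(loci),
    order = ord,
    cluster = if (is.null(clusters)) "" else clusters[names(loci)] %val% "",
    description = vcharacter(loci, function(l) l$description),
    regions = vcharacter(loci, function(l) format_regions_spec(l$regions)),
    stringsAsFactors = FALSE)
  utils::write.table(ldf, locus_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(feature_table = feature_path, locus_table = locus_path))
}

# elementwise NA -> replacement
`%val%` <- function(x, repl) { x[is.na(x)] <- repl; x }
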