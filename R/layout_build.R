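# Figure assembly: turns an ordered locus set (comparative mode) or a
# single locus plus tracks (browser mode) into an `lv_layout` consumed by
# the renderer. All geometry is computed here; rendering adds nothing.

row_metrics <- function(config) {
  box_h <- text_height_units(config$label_fontsize)
  list(
    box_h = box_h,
    tier_gap = 0.3,
    label_area = 2 * (box_h + 0.3) + 0.8,
    gene_h = config$gene_height,
    strip_gap = 1.0,
    strip_h = 0.9,
    axis_gap = 1.2
  )
}

#' Build the comparative figure layout
#'
#' Loci are drawn one row each, in the given order, against a single shared
#' bp scale (the longest displayed row spans the full drawable width).
#' In `"full"` mode each row carries a coordinate axis and a functional
#' category strip; `"compact"` mode hides both and adds one global scale
#' line at the bottom.
#'
#' @param loci an `lv_locus_set`, already in display order, with `group_id`
#'   and `group_class` filled on CDS features
#' @param config an `lv_config` (see [load_profile()])
#' @param mode "full" or "compact" (defaults to `config$mode`)
#' @return an `lv_layout`
#' @export
build_layout <- function(loci, config = load_profile(), mode = NULL) {
  mode <- mode %||% config$mode
  if (!mode %in% c("full", "compact")) stop2("mode must be 'full' or 'compact'")
  rm_ <- row_metrics(config)
  margin <- config$margin_units
  id_gutter <- max(text_width_units(names(loci), config$annotation_fontsize)) + 2
  x0 <- margin + id_gutter
  x_max <- config$width_units - margin
  drawable <- x_max - x0
  if (drawable <= 0) stop2("canvas too narrow for the locus id gutter")

  # figure-wide scale: every row must fit
  upb <- Inf
  for (loc in loci) {
    spans <- vnumeric(seq_len(nrow(loc$regions)), function(i)
      region_span(loc$regions[i, ], loc$length_bp))
    avail <- drawable - config$region_gap_units * (nrow(loc$regions) - 1L)
    if (avail <= 0) stop2("canvas too narrow for the region gaps of '",
                          loc$locus_id, "'")
    upb <- min(upb, avail / sum(spans))
  }

  transforms <- lapply(loci, function(loc)
    make_region_transform(loc, upb, x0, config$region_gap_units))

  # collect drawn feature extents (merged pieces) for visibility + connectors
  row_feats <- vector("list", length(loci))
  for (r in seq_along(loci)) {
    ft <- loci[[r]]$features
    rows <- list()
    if (nrow(ft)) for (i in seq_len(nrow(ft))) {
      ext <- feature_extent(transforms[[r]], ft$start[i], ft$end[i], ft$wraps[i])
      if (is.null(ext)) next
      for (k in seq_len(nrow(ext)))
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = ft$feature_id[i], piece = k,
          type = ft$type[i], strand = ft$strand[i],
          label = ft$label[i], group_id = ft$group_id[i],
          group_class = ft$group_class[i], category = ft$category[i],
          hypothetical = ft$hypothetical[i], show_label = ft$show_label[i],
          x1 = ext$x1[k], x2 = ext$x2[k],
          clip_left = ext$clip_left[k], clip_right = ext$clip_right[k],
          stringsAsFactors = FALSE)
    }
    row_feats[[r]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  # label visibility over the whole figure (reading order), on piece 1
  vis_rows <- list()
  for (r in seq_along(row_feats)) {
    rf <- row_feats[[r]]
    if (is.null(rf)) next
    p1 <- rf[rf$piece == 1, , drop = FALSE]
    p1$row <- r
    vis_rows[[length(vis_rows) + 1L]] <- p1
  }
  all_feats <- if (length(vis_rows)) do.call(rbind, vis_rows) else NULL
  if (!is.null(all_feats)) all_feats$visible <- label_visibility(all_feats)

  rows_out <- vector("list", length(loci))
  y <- margin
  legend_cats <- NULL
  for (r in seq_along(loci)) {
    loc <- loci[[r]]
    y_tier1 <- y + 2 * (rm_$box_h + rm_$tier_gap)
    arrows_top <- y + rm_$label_area
    y_mid <- arrows_top + rm_$gene_h / 2
    arrows_bot <- arrows_top + rm_$gene_h
    rf <- row_feats[[r]]
    arrows <- list()
    if (!is.null(rf)) for (i in seq_len(nrow(rf))) {
      poly <- arrow_geometry(rf$x1[i], rf$x2[i], y_mid, rm_$gene_h,
                             rf$strand[i], config$head_units,
                             rf$clip_left[i], rf$clip_right[i])
      arrows[[length(arrows) + 1L]] <- list(
        feature_id = rf$feature_id[i], group_id = rf$group_id[i],
        group_class = rf$group_class[i], type = rf$type[i], polygon = poly)
    }
    # labels: visible piece-1 features of this row
    labels <- NULL
    if (!is.null(all_feats)) {
      mine <- all_feats[all_feats$row == r & all_feats$visible, , drop = FALSE]
      if (nrow(mine)) {
        lab_in <- data.frame(text = mine$label,
                             xc = (mine$x1 + mine$x2) / 2,
                             feat_w = mine$x2 - mine$x1,
                             width = text_width_units(mine$label,
                                                      config$label_fontsize),
                             stringsAsFactors = FALSE)
        placed <- place_labels(lab_in, y_tier1, rm_$box_h, x0, x_max)
        placed$lx <- lab_in$xc
        labels <- placed[placed$placed, , drop = FALSE]
      }
    }
    strip <- NULL
    if (mode == "full" && !is.null(rf)) {
      st <- category_strip(rf[, c("category", "x1", "x2")],
                           arrows_bot + rm_$strip_gap,
                           config$category_palette)
      if (nrow(st$segments)) {
        strip <- st$segments
        legend_cats <- unique(rbind(legend_cats, st$legend))
      }
    }
    axis <- NULL
    if (mode == "full") {
      tr <- transforms[[r]]
      ay <- arrows_bot + rm_$strip_gap + rm_$strip_h + rm_$axis_gap
      axis <- list(y = ay, segments = data.frame(
        x1 = tr$offsets, x2 = tr$offsets + tr$spans * upb,
        from_bp = tr$regions$start,
        to_bp = ifelse(tr$regions$wraps_origin,
                       tr$regions$end + tr$length_bp, tr$regions$end)))
    }
    rows_out[[r]] <- list(
      locus_id = loc$locus_id, y_top = y, y_mid = y_mid,
      arrows_top = arrows_top, arrows_bottom = arrows_bot,
      transform = transforms[[r]], arrows = arrows,
      extents = rf, labels = labels, strip = strip, axis = axis)
    y <- y + config$row_height
  }

  # connectors between adjacent rows (CDS pieces with groups; every drawn
  # piece participates so wrap pieces connect too - nearest pair rule)
  conn_rows <- lapply(row_feats, function(rf) {
    if (is.null(rf)) return(data.frame(group_id = character(0),
                                       x1 = numeric(0), x2 = numeric(0)))
    rf[rf$type == "CDS", c("group_id", "x1", "x2")]
  })
  connectors <- homology_connectors(
    conn_rows,
    y_bottoms = vnumeric(rows_out, function(r) r$arrows_bottom),
    y_tops = c(0, vnumeric(rows_out, function(r) r$arrows_top))[-1])

  scale_bar <- NULL
  if (mode == "compact") {
    sb <- scale_line(upb, config$width_units, config$scalebar_fraction)
    sb$x1 <- x0
    sb$x2 <- x0 + sb$units
    sb$y <- y + 2
    y <- y + 6
    scale_bar <- sb
  }
  legend <- NULL
  if (!is.null(legend_cats) && nrow(legend_cats)) {
    legend <- legend_cats
    legend$y <- y + 3
    y <- y + 4 + 2 * ceiling(nrow(legend) / 3)
  }
  structure(list(
    mode = mode, config = config, width_units = config$width_units,
    height_units = y + margin, upb = upb, x0 = x0, x_max = x_max,
    rows = rows_out, connectors = connectors, scale_bar = scale_bar,
    legend = legend, panels = NULL
  ), class = "lv_layout")
}

#' @export
print.lv_layout <- function(x, ...) {
  cat(sprintf("<lv_layout> mode %s: %d rows%s, canvas %.0f x %.0f units\n",
              x$mode, length(x$rows),
              if (!is.null(x$panels)) sprintf(" + %d panels", length(x$panels)) else "",
              x$width_units, x$height_units))
  invisible(x)
}

#' Build the genome-browser layout for a single locus
#'
#' Panels are stacked top to bottom: functional category strip, gene map,
#' GC content, GC skew, then the supplied signal tracks in input order.
#' Centred tracks are drawn as filled area with distinct colours for
#' positive and negative relative values, and each track panel carries a
#' corner annotation with the raw minimum, maximum and mean.
#'
#' @param locus a single `lv_locus` (comparative mode handles several)
#' @param tracks list of `lv_track` signal tracks (may be empty)
#' @param config an `lv_config`
#' @param gc include the GC content / GC skew property tracks (default TRUE)
#' @return an `lv_layout` with `mode = "browser"`
#' @export
browser_panel <- function(locus, tracks = list(), config = load_profile(),
                          gc = TRUE) {
  if (inherits(locus, "lv_locus_set")) {
    if (length(locus) > 1)
      stop2("browser mode takes exactly one locus; use the comparative mode ",
            "for several")
    locus <- locus[[1]]
  }
  single <- locus_set(list(locus))
  base <- build_layout(single, config, mode = "full")
  gene_row <- base$rows[[1]]
  y <- gene_row$axis$y + 4

  panels <- list()
  add_track_panel <- function(track, title, centred_colors = TRUE,
                              color = config$signal_color) {
    h <- config$track_height
    xs <- bp_to_x(gene_row$transform, track$positions)
    keep <- !is.na(xs)
    v <- track$values[keep]; xs <- xs[keep]
    bw <- track$step * base$upb
    y_base <- if (track$centred) y + h / 2 else y + h
    vmax <- max(abs(v), 1e-12)
    scale <- (h / 2 * 0.9) / vmax
    if (!track$centred) scale <- (h * 0.9) / max(v, 1e-12)
    bars <- data.frame(
      x1 = xs, x2 = pmin(xs + bw, gene_row$transform$x0 + gene_row$transform$width),
      y0 = y_base, y1 = y_base - v * scale,
      positive = v > 0, stringsAsFactors = FALSE)
    ann <- track$annotation %||% list(mean = track$mean_value,
                                      min = track$value_range[1],
                                      max = track$value_range[2])
    annotation <- sprintf("min: %s; max: %s; mean: %s",
                          signif(ann$min, 4), signif(ann$max, 4),
                          signif(ann$mean, 4))
    panels[[length(panels) + 1L]] <<- list(
      kind = track$kind, title = title, y_top = y, height = h,
      y_base = y_base, bars = bars, centred = track$centred,
      annotation = annotation, centred_colors = centred_colors,
      color = color)
    y <<- y + h + 3
  }

  if (gc) {
    if (is.na(locus$sequence))
      stop2("locus '", locus$locus_id, "' has no sequence; GC tracks need one")
    win <- locus$regions[1, ]
    seq_used <- if (nrow(locus$regions) == 1 && !win$wraps_origin)
      substr(locus$sequence, win$start + 1L, win$end) else locus$sequence
    off <- if (nrow(locus$regions) == 1 && !win$wraps_origin) win$start else 0L
    gct <- gc_content_track(seq_used, locus$locus_id, config$gc_window)
    gst <- gc_skew_track(seq_used, locus$locus_id, config$gc_window)
    gct$positions <- gct$positions + off
    gst$positions <- gst$positions + off
    panel_w <- gene_row$transform$width
    gct <- centre_track(smooth_adaptive(gct, panel_w, config$points_per_unit))
    gst <- centre_track(smooth_adaptive(gst, panel_w, config$points_per_unit))
    add_track_panel(gct, "GC content")
    add_track_panel(gst, "GC skew")
  }
  if (length(tracks)) for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    tr2 <- smooth_adaptive(tr, gene_row$transform$width, config$points_per_unit)
    add_track_panel(tr2, names(tracks)[i] %||% sprintf("signal %d", i),
                    centred_colors = FALSE)
  }

  base$mode <- "browser"
  base$panels <- panels
  base$height_units <- y + config$margin_units
  base
}
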