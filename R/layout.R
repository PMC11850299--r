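# Layout engine: turns ordered loci, group classes and signal tracks into a
# resolution-independent geometric structure (canvas units are mm, y grows
# downward from the top margin). The renderer consumes this structure
# verbatim, so every geometric invariant (label non-overlap, connector
# validity, shared bp scale) is testable without touching a PDF.

#' Build the bp -> canvas-unit transform for one locus row
#'
#' Display regions are laid left-to-right in their given order, separated by
#' a fixed gap; within a region the map is affine at `units_per_bp`. A
#' wrapping region is continuous across the origin (end concatenated after
#' start, no gap).
#'
#' @param locus an `lv_locus`
#' @param units_per_bp figure-wide scale (canvas units per base)
#' @param x0 left edge of the row in canvas units
#' @param gap_units gap between consecutive regions
#' @return an `lv_transform`
#' @export
make_region_transform <- function(locus, units_per_bp, x0, gap_units = 2) {
  regions <- locus$regions
  spans <- vnumeric(seq_len(nrow(regions)), function(i)
    region_span(regions[i, ], locus$length_bp))
  if (sum(spans) <= 0) stop2("locus '", locus$locus_id, "': zero-length displayed span")
  offsets <- x0 + c(0, cumsum(utils::head(spans, -1) * units_per_bp +
                                gap_units))
  structure(list(locus_id = locus$locus_id, length_bp = locus$length_bp,
                 regions = regions, spans = spans, offsets = offsets,
                 upb = units_per_bp, x0 = x0, gap = gap_units,
                 width = sum(spans) * units_per_bp +
                   gap_units * (nrow(regions) - 1L)),
            class = "lv_transform")
}

# displayed offset (in bp from region start) of position bp within region i,
# NA when bp is outside the region
region_offset <- function(tr, i, bp) {
  r <- tr$regions[i, ]
  if (r$wraps_origin) {
    ifelse(bp >= r$start, bp - r$start,
           ifelse(bp < r$end, (tr$length_bp - r$start) + bp, NA_real_))
  } else {
    ifelse(bp >= r$start & bp <= r$end, bp - r$start, NA_real_)
  }
}

#' Map base positions to canvas x coordinates
#'
#' Positions outside every display region map to NA. For a position covered
#' by several regions the first region (in display order) wins.
#' @param tr an `lv_transform`
#' @param bp numeric vector of 0-based positions
#' @return numeric vector of x coordinates in canvas units
#' @export
bp_to_x <- function(tr, bp) {
  out <- rep(NA_real_, length(bp))
  for (i in seq_len(nrow(tr$regions))) {
    off <- region_offset(tr, i, bp)
    fill <- is.na(out) & !is.na(off)
    out[fill] <- tr$offsets[i] + off[fill] * tr$upb
  }
  out
}

# x-extent of a feature clipped to the display regions; returns rows
# (one per region the feature intersects) with clip flags
feature_extent <- function(tr, start, end, wraps) {
  L <- tr$length_bp
  # feature occupies [start,end) or, wrapping, [start,L) + [0,end)
  # pieces carry flags marking artificial cut edges (origin seam of a
  # wrapping feature); merging contiguous pieces clears the seam flags
  fsegs <- if (wraps) list(list(span = c(start, L), open_right = TRUE),
                           list(span = c(0, end), open_left = TRUE))
           else list(list(span = c(start, end)))
  out <- list()
  for (i in seq_len(nrow(tr$regions))) {
    r <- tr$regions[i, ]
    rsegs <- if (r$wraps_origin) list(c(r$start, L), c(0, r$end))
             else list(c(r$start, r$end))
    for (fs in fsegs) for (rs in rsegs) {
      s <- max(fs$span[1], rs[1]); e <- min(fs$span[2], rs[2])
      if (e <= s) next
      x1 <- tr$offsets[i] + region_offset(tr, i, s) * tr$upb
      x2 <- x1 + (e - s) * tr$upb
      out[[length(out) + 1L]] <- data.frame(
        region = i, x1 = x1, x2 = x2,
        clip_left = s > fs$span[1] || isTRUE(fs$open_left),
        clip_right = e < fs$span[2] || isTRUE(fs$open_right))
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  # merge contiguous pieces (wrap feature inside wrap region joins seamlessly)
  res <- res[order(res$x1), , drop = FALSE]
  merged <- res[1, , drop = FALSE]
  if (nrow(res) > 1) for (k in 2:nrow(res)) {
    last <- nrow(merged)
    if (abs(res$x1[k] - merged$x2[last]) < 1e-9) {
      merged$x2[last] <- res$x2[k]
      merged$clip_right[last] <- res$clip_right[k]
    } else merged <- rbind(merged, res[k, ])
  }
  merged
}

#' Gene-arrow polygon
#'
#' Strand "+" points right, "-" points left; the head length is capped at
#' the drawn feature length so short genes degrade to triangles. A clipped
#' edge is drawn flat (headless).
#'
#' @param x1,x2 drawn x-extent (canvas units), x1 < x2
#' @param y_mid vertical centre of the row
#' @param height full arrow height
#' @param strand "+" or "-"
#' @param head_units preferred head length in canvas units
#' @param clip_left,clip_right whether that edge was produced by clipping
#' @return matrix with columns x, y (closed polygon, 7 or 4 vertices)
#' @export
arrow_geometry <- function(x1, x2, y_mid, height, strand, head_units = 2,
                           clip_left = FALSE, clip_right = FALSE) {
  hh <- height / 2          # head half-height
  bh <- height * 0.32       # body half-height
  len <- x2 - x1
  head <- min(head_units, len)
  headless <- (strand == "+" && clip_right) || (strand == "-" && clip_left)
  if (headless) {
    return(cbind(x = c(x1, x2, x2, x1), y = y_mid + c(-bh, -bh, bh, bh)))
  }
  if (strand == "+") {
    xh <- x2 - head
    cbind(x = c(x1, xh, xh, x2, xh, xh, x1),
          y = y_mid + c(-bh, -bh, -hh, 0, hh, bh, bh))
  } else {
    xh <- x1 + head
    cbind(x = c(x2, xh, xh, x1, xh, xh, x2),
          y = y_mid + c(-bh, -bh, -hh, 0, hh, bh, bh))
  }
}

#' Decide which feature labels are shown
#'
#' The rules of the comparative figure: hypothetical proteins and proteins
#' of unknown function are hidden; labels of conserved groups are shown only
#' at their first occurrence in reading order (top row first, left to
#' right), since homology connectors indicate later occurrences; variable
#' and intermediate features keep their labels. A feature-table
#' `show_label` value overrides everything.
#'
#' @param feature_rows data.frame with columns `label`, `group_id`,
#'   `group_class`, `hypothetical`, `show_label`, `row`, `x1` (rows already
#'   in final display order)
#' @return logical vector of visibility flags
#' @export
label_visibility <- function(feature_rows) {
  fr <- feature_rows
  vis <- rep(TRUE, nrow(fr))
  vis[is.na(fr$label) | fr$label == ""] <- FALSE
  vis[fr$hypothetical] <- FALSE
  # conserved: first occurrence in reading order only
  ord <- order(fr$row, fr$x1)
  seen <- character(0)
  for (i in ord) {
    if (identical(fr$group_class[i], "conserved") && !is.na(fr$group_id[i])) {
      if (fr$group_id[i] %in% seen) vis[i] <- FALSE
      else seen <- c(seen, fr$group_id[i])
    }
  }
  override <- !is.na(fr$show_label)
  vis[override] <- fr$show_label[override]
  vis
}

#' Greedy two-tier label placement
#'
#' Labels are processed left to right by feature start. The preferred slot
#' is centred above the feature on tier 1; on collision with an already
#' placed label the box slides horizontally (right, then left) by up to half
#' the feature's drawn width; if it still collides it is promoted to tier 2
#' (one label height higher, drawn with a thin leader line); if tier 2
#' collides too, the label is dropped with a warning. The result contains no
#' overlapping boxes by construction.
#'
#' @param labels data.frame with columns `text`, `xc` (preferred centre),
#'   `feat_w` (drawn feature width), `width` (text width), for one row of
#'   the figure
#' @param y_tier1 baseline y of tier 1 (canvas units; y grows downward)
#' @param box_h label box height
#' @param x_min,x_max horizontal canvas bounds for label boxes
#' @return data.frame(text, x1, x2, tier, y, placed, leader)
#' @export
place_labels <- function(labels, y_tier1, box_h, x_min, x_max) {
  n <- nrow(labels)
  res <- data.frame(text = labels$text,
                    x1 = NA_real_, x2 = NA_real_, tier = NA_integer_,
                    y = NA_real_, placed = FALSE, leader = FALSE,
                    stringsAsFactors = FALSE)
  if (!n) return(res)
  pad <- 0.4  # horizontal clearance between boxes
  placed <- list()
  collides <- function(x1, x2, tier) {
    for (b in placed)
      if (b$tier == tier && x1 < b$x2 + pad && x2 > b$x1 - pad) return(TRUE)
    FALSE
  }
  try_tier <- function(xc, w, max_slide, tier) {
    base <- max(x_min, min(xc - w / 2, x_max - w))
    for (shift in unique(c(0, seq(0.5, max_slide, by = 0.5),
                           -seq(0.5, max_slide, by = 0.5)))) {
      x1 <- base + shift
      x2 <- x1 + w
      if (x1 < x_min - 1e-9 || x2 > x_max + 1e-9) next
      if (!collides(x1, x2, tier)) return(c(x1, x2))
    }
    NULL
  }
  ord <- order(labels$xc)
  dropped <- 0L
  for (i in ord) {
    w <- labels$width[i]
    if (w > x_max - x_min) { dropped <- dropped + 1L; next }
    max_slide <- max(labels$feat_w[i] / 2, 0.5)
    hit <- try_tier(labels$xc[i], w, max_slide, 1L)
    tier <- 1L
    if (is.null(hit)) { hit <- try_tier(labels$xc[i], w, max_slide, 2L); tier <- 2L }
    if (is.null(hit)) { dropped <- dropped + 1L; next }
    res$x1[i] <- hit[1]; res$x2[i] <- hit[2]; res$tier[i] <- tier
    res$y[i] <- y_tier1 - (tier - 1L) * (box_h + 0.3)
    res$placed[i] <- TRUE
    res$leader[i] <- tier == 2L
    placed[[length(placed) + 1L]] <- list(x1 = hit[1], x2 = hit[2], tier = tier)
  }
  if (dropped)
    warn2(dropped, " label(s) dropped to avoid overlaps")
  res
}

#' Homology connectors between vertically adjacent rows
#'
#' For every pair of adjacent rows and every group present in both, one
#' quadrilateral joins the x-extents of the two features. When a group has
#' several copies in a row the nearest pair by x-midpoint distance is
#' joined. Connectors never skip rows; transitive chains convey
#' longer-range homology.
#'
#' @param rows list (in display order) of data.frames with columns
#'   `group_id`, `x1`, `x2` (drawn extents of grouped features)
#' @param y_bottoms,y_tops numeric: bottom y of each row's arrows and top y
#'   of the next row's arrows (lengths = rows count, count - 1 used)
#' @return data.frame(group_id, row_top, ax1, ax2, bx1, bx2, y1, y2)
#' @export
homology_connectors <- function(rows, y_bottoms, y_tops) {
  out <- list()
  if (length(rows) < 2) return(connector_df())
  for (r in seq_len(length(rows) - 1L)) {
    a <- rows[[r]]; b <- rows[[r + 1L]]
    shared <- intersect(a$group_id[!is.na(a$group_id)],
                        b$group_id[!is.na(b$group_id)])
    for (g in shared) {
      ai <- which(a$group_id == g)
      bi <- which(b$group_id == g)
      mids_a <- (a$x1[ai] + a$x2[ai]) / 2
      mids_b <- (b$x1[bi] + b$x2[bi]) / 2
      dd <- abs(outer(mids_a, mids_b, "-"))
      k <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      ia <- ai[k[1]]; ib <- bi[k[2]]
      out[[length(out) + 1L]] <- data.frame(
        group_id = g, row_top = r,
        ax1 = a$x1[ia], ax2 = a$x2[ia], bx1 = b$x1[ib], bx2 = b$x2[ib],
        y1 = y_bottoms[r], y2 = y_tops[r + 1L], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(connector_df())
  do.call(rbind, out)
}

connector_df <- function() {
  data.frame(group_id = character(0), row_top = integer(0),
             ax1 = numeric(0), ax2 = numeric(0), bx1 = numeric(0),
             bx2 = numeric(0), y1 = numeric(0), y2 = numeric(0))
}

# PHROG functional-category palette (defaults; user-overridable in config)
PHROG_PALETTE <- c(
  "head and packaging" = "#4575B4",
  "connector" = "#91BFDB",
  "tail" = "#74ADD1",
  "lysis" = "#D73027",
  "DNA, RNA and nucleotide metabolism" = "#FDAE61",
  "transcription regulation" = "#FEE090",
  "moron, auxiliary metabolic gene and host takeover" = "#984EA3",
  "integration and excision" = "#4DAF4A",
  "other" = "#999999",
  "unknown function" = "#CCCCCC"
)

#' Functional-category strip segments for one row
#'
#' One coloured segment under each categorized ORF, spanning its drawn
#' x-extent. Unknown categories render in the reserved "other" colour with
#' a warning. The strip is suppressed entirely in compact mode (handled by
#' the layout builder).
#' @param feats data.frame with columns `category`, `x1`, `x2`
#' @param y vertical position of the strip
#' @param palette named colour vector (default PHROG categories)
#' @return list(segments = data.frame(x1, x2, y, category, color),
#'   legend = data.frame(category, color))
#' @export
category_strip <- function(feats, y, palette = PHROG_PALETTE) {
  keep <- !is.na(feats$category) & feats$category != ""
  feats <- feats[keep, , drop = FALSE]
  if (!nrow(feats))
    return(list(segments = data.frame(x1 = numeric(0), x2 = numeric(0),
                                      y = numeric(0), category = character(0),
                                      color = character(0)),
                legend = data.frame(category = character(0), color = character(0))))
  unknown <- setdiff(unique(feats$category), names(palette))
  if (length(unknown))
    warn2("unknown functional categor", if (length(unknown) > 1) "ies: " else "y: ",
          paste(unknown, collapse = ", "), " (rendered in the 'other' colour)")
  color <- unname(palette[feats$category])
  color[is.na(color)] <- palette[["other"]]
  segs <- data.frame(x1 = feats$x1, x2 = feats$x2, y = y,
                     category = feats$category, color = color,
                     stringsAsFactors = FALSE)
  cats <- unique(segs[, c("category", "color")])
  rownames(cats) <- NULL
  list(segments = segs, legend = cats)
}

#' Scale-bar specification
#'
#' The bar length is the largest "nice" value (1, 2 or 5 times a power of
#' ten, in bp) not exceeding `fraction` of the canvas width; the unit label
#' switches to kbp at 1000 bp.
#' @param units_per_bp figure scale
#' @param width_units canvas width
#' @param fraction maximal bar fraction of the width (default 0.25)
#' @return list(bp, units, label)
#' @export
scale_line <- function(units_per_bp, width_units, fraction = 0.25) {
  max_bp <- fraction * width_units / units_per_bp
  if (max_bp < 1) stop2("canvas too narrow for a scale bar")
  k <- floor(log10(max_bp))
  cand <- as.vector(outer(c(1, 2, 5), 10^(seq.int(max(0, k - 1), k))))
  bp <- max(cand[cand <= max_bp + 1e-9])
  label <- if (bp >= 1000) sprintf("%g kbp", bp / 1000) else sprintf("%g bp", bp)
  list(bp = bp, units = bp * units_per_bp, label = label)
}
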