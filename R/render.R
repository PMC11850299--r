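# Rendering: deterministic colour assignment for homology groups and a
# purpose-built minimal PDF 1.4 writer. Streams are uncompressed and the
# document timestamp is pinned by the style, so identical layouts produce
# byte-identical files; text is written as text objects (editable in vector
# editors) in base-14 Helvetica.

#' Assign colours to homology groups
#'
#' In `"variable"` highlight mode every variable (and, by default,
#' intermediate) group receives its own colour and conserved groups share
#' the single conserved grey; `"conserved"` mode inverts the assignment.
#' Hues are equally spaced (360/n degrees apart, guaranteeing pairwise hue
#' separation of at least 360/(n+1) for n coloured groups) and the starting
#' hue is derived from the seed by golden-angle stepping, so the palette is
#' deterministic for a given seed.
#'
#' @param classes data.frame from [classify_protein_groups()] (columns
#'   `group_id`, `class`), or a named class vector keyed by group id
#' @param highlight "variable" (default) or "conserved"
#' @param seed palette seed (integer)
#' @param conserved_color colour of the non-highlighted groups
#' @param color_intermediate also colour intermediate groups in variable
#'   mode (default TRUE)
#' @return named character vector group_id -> hex colour
#' @export
assign_group_colors <- function(classes, highlight = c("variable", "conserved"),
                                seed = 1, conserved_color = "#B4B4B4",
                                color_intermediate = TRUE) {
  highlight <- match.arg(highlight)
  if (is.data.frame(classes)) {
    cls <- classes$class
    names(cls) <- classes$group_id
    cls <- cls[!duplicated(names(cls))]
  } else cls <- classes
  groups <- sort(names(cls))
  cls <- cls[groups]
  coloured <- if (highlight == "variable") {
    cls == "variable" | (color_intermediate & cls == "intermediate")
  } else cls == "conserved"
  out <- stats::setNames(rep(conserved_color, length(groups)), groups)
  n <- sum(coloured)
  if (n > 0) {
    offset <- (seed * 137.50776405) %% 360
    hues <- (offset + (seq_len(n) - 1) * 360 / n) %% 360
    out[coloured] <- grDevices::hsv(hues / 360, s = 0.55, v = 0.92)
  }
  out
}

# ---- minimal PDF writer ------------------------------------------------

MM_TO_PT <- 72 / 25.4

pdf_escape <- function(s) gsub("([()\\\\])", "\\\\\\1", s)

fmt <- function(x) sprintf("%.3f", x)

hex_to_rgb01 <- function(hex) as.vector(grDevices::col2rgb(hex)) / 255

new_pdf_canvas <- function(height_units) {
  env <- new.env(parent = emptyenv())
  env$ops <- character(1024)   # amortized growth; cv_ops() trims
  env$n <- 0L
  env$H <- height_units
  env
}

cv_push <- function(cv, ...) {
  if (cv$n == length(cv$ops)) cv$ops <- c(cv$ops, character(length(cv$ops)))
  cv$n <- cv$n + 1L
  cv$ops[cv$n] <- paste(...)
}

cv_ops <- function(cv) cv$ops[seq_len(cv$n)]

# y flip: layout y grows downward from the top; PDF origin is bottom-left
cv_y <- function(cv, y) (cv$H - y) * MM_TO_PT

cv_poly <- function(cv, xs, ys, fill = NULL, stroke = NULL, lw = 0.3) {
  x <- xs * MM_TO_PT
  y <- cv_y(cv, ys)
  cv_push(cv, fmt(x[1]), fmt(y[1]), "m")
  for (i in seq_along(x)[-1]) cv_push(cv, fmt(x[i]), fmt(y[i]), "l")
  cv_push(cv, "h")
  mode <- ""
  if (!is.null(fill)) {
    rgb <- hex_to_rgb01(fill)
    cv_push(cv, fmt(rgb[1]), fmt(rgb[2]), fmt(rgb[3]), "rg")
    mode <- "f"
  }
  if (!is.null(stroke)) {
    rgb <- hex_to_rgb01(stroke)
    cv_push(cv, fmt(rgb[1]), fmt(rgb[2]), fmt(rgb[3]), "RG")
    cv_push(cv, fmt(lw), "w")
    mode <- if (mode == "f") "B" else "S"
  }
  cv_push(cv, mode)
}

cv_rect <- function(cv, x1, y1, x2, y2, fill = NULL, stroke = NULL, lw = 0.3) {
  cv_poly(cv, c(x1, x2, x2, x1), c(y1, y1, y2, y2), fill, stroke, lw)
}

cv_line <- function(cv, x1, y1, x2, y2, color = "#000000", lw = 0.3) {
  rgb <- hex_to_rgb01(color)
  cv_push(cv, fmt(rgb[1]), fmt(rgb[2]), fmt(rgb[3]), "RG", fmt(lw), "w")
  cv_push(cv, fmt(x1 * MM_TO_PT), fmt(cv_y(cv, y1)), "m",
          fmt(x2 * MM_TO_PT), fmt(cv_y(cv, y2)), "l", "S")
}

cv_text <- function(cv, x, y_baseline, s, size_pt, color = "#000000",
                    font = "F1") {
  if (is.na(s) || !nzchar(s)) return(invisible())
  rgb <- hex_to_rgb01(color)
  cv_push(cv, "BT", paste0("/", font), fmt(size_pt), "Tf",
          fmt(rgb[1]), fmt(rgb[2]), fmt(rgb[3]), "rg",
          fmt(x * MM_TO_PT), fmt(cv_y(cv, y_baseline)), "Td",
          paste0("(", pdf_escape(s), ")"), "Tj", "ET")
}

write_pdf_file <- function(cv, width_units, height_units, path, timestamp) {
  stream <- paste(cv_ops(cv), collapse = "\n")
  W <- fmt(width_units * MM_TO_PT)
  H <- fmt(height_units * MM_TO_PT)
  objs <- list(
    "<< /Type /Catalog /Pages 2 0 R >>",
    "<< /Type /Pages /Kids [3 0 R] /Count 1 >>",
    paste0("<< /Type /Page /Parent 2 0 R /MediaBox [0 0 ", W, " ", H,
           "] /Contents 4 0 R /Resources << /Font << /F1 5 0 R /F2 6 0 R >> >> >>"),
    paste0("<< /Length ", nchar(stream, type = "bytes"), " >>\nstream\n",
           stream, "\nendstream"),
    "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>",
    "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica-Bold >>",
    paste0("<< /Producer (lociview) /CreationDate (", timestamp,
           ") /ModDate (", timestamp, ") >>")
  )
  head <- "%PDF-1.4\n"
  body <- character(length(objs))
  offsets <- integer(length(objs))
  pos <- nchar(head, type = "bytes")
  for (i in seq_along(objs)) {
    body[i] <- paste0(i, " 0 obj\n", objs[[i]], "\nendobj\n")
    offsets[i] <- pos
    pos <- pos + nchar(body[i], type = "bytes")
  }
  xref_pos <- pos
  xref <- paste0("xref\n0 ", length(objs) + 1, "\n",
                 "0000000000 65535 f \n",
                 paste(sprintf("%010d 00000 n ", offsets), collapse = "\n"),
                 "\n")
  trailer <- paste0("trailer\n<< /Size ", length(objs) + 1,
                    " /Root 1 0 R /Info ", length(objs), " 0 R >>\n",
                    "startxref\n", xref_pos, "\n%%EOF\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(head, paste(body, collapse = ""), xref, trailer)),
           con)
  invisible(path)
}

# ---- layout -> PDF -----------------------------------------------------

#' Render a layout to a single-page vector PDF
#'
#' The page width follows the configuration profile and the height grows to
#' fit the layout. All elements are vector primitives; text is written as
#' text objects so the output stays editable in vector image editors.
#' Rendering is a pure function of (layout, colours, style): with the
#' default pinned timestamp, identical inputs give byte-identical files.
#'
#' @param layout an `lv_layout`
#' @param colors named group_id -> colour map from [assign_group_colors()]
#' @param path output PDF path
#' @param timestamp PDF metadata timestamp (pinned by default for
#'   reproducibility; pass e.g. `format(Sys.time(), "D:%Y%m%d%H%M%SZ")` for
#'   wall-clock metadata)
#' @return `path`, invisibly
#' @export
render_pdf <- function(layout, colors = character(0), path,
                       timestamp = layout$config$timestamp) {
  config <- layout$config
  cv <- new_pdf_canvas(layout$height_units)
  conserved_col <- config$conserved_color

  # connectors first (beneath arrows)
  cn <- layout$connectors
  if (!is.null(cn) && nrow(cn)) for (i in seq_len(nrow(cn))) {
    cv_poly(cv, c(cn$ax1[i], cn$ax2[i], cn$bx2[i], cn$bx1[i]),
            c(cn$y1[i], cn$y1[i], cn$y2[i], cn$y2[i]),
            fill = config$connector_color)
  }

  for (row in layout$rows) {
    cv_text(cv, config$margin_units, row$y_mid + 1, row$locus_id,
            config$annotation_fontsize)
    for (a in row$arrows) {
      fill <- if (!is.na(a$group_id) && a$group_id %in% names(colors))
        colors[[a$group_id]] else conserved_col
      if (a$type != "CDS") fill <- "#FFFFFF"
      cv_poly(cv, a$polygon[, "x"], a$polygon[, "y"], fill = fill,
              stroke = "#3C3C3C", lw = 0.25)
    }
    if (!is.null(row$labels) && nrow(row$labels)) {
      lb <- row$labels
      for (i in seq_len(nrow(lb))) {
        if (lb$leader[i])
          cv_line(cv, lb$lx[i], row$arrows_top - 0.3, lb$lx[i],
                  lb$y[i] + 0.3, color = "#9B9B9B", lw = 0.15)
        cv_text(cv, lb$x1[i], lb$y[i], lb$text[i], config$label_fontsize)
      }
    }
    if (!is.null(row$strip) && nrow(row$strip)) {
      st <- row$strip
      for (i in seq_len(nrow(st)))
        cv_line(cv, st$x1[i], st$y[i], st$x2[i], st$y[i],
                color = st$color[i], lw = 0.9)
    }
    if (!is.null(row$axis)) {
      ax <- row$axis
      for (i in seq_len(nrow(ax$segments))) {
        cv_line(cv, ax$segments$x1[i], ax$y, ax$segments$x2[i], ax$y,
                color = "#5A5A5A", lw = 0.25)
        cv_text(cv, ax$segments$x1[i], ax$y + 2,
                format(ax$segments$from_bp[i] + 1, big.mark = ""),
                config$annotation_fontsize - 1, color = "#5A5A5A")
        to_lab <- format(ax$segments$to_bp[i], big.mark = "")
        cv_text(cv, ax$segments$x2[i] -
                  text_width_units(to_lab, config$annotation_fontsize - 1),
                ax$y + 2, to_lab, config$annotation_fontsize - 1,
                color = "#5A5A5A")
      }
    }
  }

  if (!is.null(layout$scale_bar)) {
    sb <- layout$scale_bar
    cv_line(cv, sb$x1, sb$y, sb$x2, sb$y, color = "#000000", lw = 0.5)
    cv_line(cv, sb$x1, sb$y - 0.8, sb$x1, sb$y + 0.8, lw = 0.5)
    cv_line(cv, sb$x2, sb$y - 0.8, sb$x2, sb$y + 0.8, lw = 0.5)
    cv_text(cv, sb$x2 + 2, sb$y + 0.8, sb$label, config$annotation_fontsize)
  }

  if (!is.null(layout$legend)) {
    lg <- layout$legend
    x <- layout$x0
    yl <- lg$y[1]
    for (i in seq_len(nrow(lg))) {
      cv_line(cv, x, yl, x + 4, yl, color = lg$color[i], lw = 0.9)
      cv_text(cv, x + 5, yl + 0.7, lg$category[i], config$annotation_fontsize)
      x <- x + 7 + text_width_units(lg$category[i], config$annotation_fontsize)
      if (x > layout$x_max - 30) { x <- layout$x0; yl <- yl + 2.5 }
    }
  }

  if (!is.null(layout$panels)) for (p in layout$panels) {
    cv_text(cv, layout$x0, p$y_top - 0.8, p$title, config$annotation_fontsize)
    if (nrow(p$bars)) {
      pos_col <- if (p$centred_colors) layout$config$positive_color else p$color
      neg_col <- if (p$centred_colors) layout$config$negative_color else p$color
      for (i in seq_len(nrow(p$bars))) {
        b <- p$bars[i, ]
        if (abs(b$y1 - b$y0) < 1e-9) next
        cv_rect(cv, b$x1, b$y0, b$x2, b$y1,
                fill = if (b$positive) pos_col else neg_col)
      }
    }
    cv_line(cv, layout$x0, p$y_base, layout$x0 + layout$rows[[1]]$transform$width,
            p$y_base, color = "#8C8C8C", lw = 0.2)
    ann_w <- text_width_units(p$annotation, config$annotation_fontsize - 1)
    cv_text(cv, layout$x_max - ann_w, p$y_top + p$height + 1.6,
            p$annotation, config$annotation_fontsize - 1, color = "#5A5A5A")
  }

  write_pdf_file(cv, layout$width_units, layout$height_units, path, timestamp)
}
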