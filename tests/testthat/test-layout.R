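# Layout engine: coordinate transforms, arrow geometry, label visibility
# and placement, homology connectors, category strips, scale bar, browser
# panels, and the whole-figure invariants.

simple_locus <- function(id = "X", len = 1000L, feats = NULL, circular = FALSE,
                         regions = NULL) {
  l <- new_locus(id, sequence = strrep("A", len), circular = circular,
                 regions = regions)
  if (!is.null(feats)) l$features <- feats
  l
}

feat_row <- function(id, start, end, strand = "+", label = id,
                     group = NA_character_, class = NA_character_,
                     hypo = FALSE, wraps = FALSE, show = NA,
                     category = NA_character_, type = "CDS") {
  data.frame(feature_id = id, type = type, start = as.integer(start),
             end = as.integer(end), strand = strand, label = label,
             protein_seq = "M", group_id = group, group_class = class,
             category = category, hypothetical = hypo, wraps = wraps,
             show_label = show, stringsAsFactors = FALSE)
}

test_that("coordinate map is affine inside a region", {
  l <- simple_locus(len = 1000L)
  tr <- make_region_transform(l, units_per_bp = 0.1, x0 = 0)
  expect_equal(bp_to_x(tr, 500), 50)
  expect_equal(bp_to_x(tr, 0), 0)
  expect_equal(bp_to_x(tr, c(100, 200)), c(10, 20))
  expect_true(is.na(bp_to_x(tr, 1500)))
})

test_that("multiple regions share the figure scale and a fixed gap", {
  l <- simple_locus(len = 1000L,
                    regions = data.frame(start = c(0L, 500L),
                                         end = c(400L, 900L),
                                         wraps_origin = FALSE))
  tr <- make_region_transform(l, units_per_bp = 0.1, x0 = 0, gap_units = 2)
  # both regions: 400 bp at 0.1 u/bp = 40 units; second starts after gap
  expect_equal(bp_to_x(tr, 0), 0)
  expect_equal(bp_to_x(tr, 500), 42)
  expect_equal((bp_to_x(tr, 300) - bp_to_x(tr, 100)) / 200,
               (bp_to_x(tr, 800) - bp_to_x(tr, 600)) / 200)
})

test_that("a wrapping region is continuous across the origin", {
  l <- simple_locus(len = 100L, circular = TRUE,
                    regions = data.frame(start = 90L, end = 10L,
                                         wraps_origin = TRUE))
  tr <- make_region_transform(l, units_per_bp = 1, x0 = 0)
  # displayed span is 20 bp: [90,100) then [0,10)
  expect_equal(tr$width, 20)
  expect_equal(bp_to_x(tr, 90), 0)
  expect_equal(bp_to_x(tr, 99), 9)
  expect_equal(bp_to_x(tr, 0), 10)   # seam: continuous, no gap
  expect_equal(bp_to_x(tr, 9), 19)
})

test_that("arrows point with the strand and degrade to triangles", {
  p <- arrow_geometry(0, 10, y_mid = 5, height = 3, strand = "+",
                      head_units = 2)
  expect_equal(nrow(p), 7L)
  expect_equal(max(p[, "x"]), 10)     # tip on the right
  expect_equal(unname(p[4, "x"]), 10)
  m <- arrow_geometry(0, 10, y_mid = 5, height = 3, strand = "-",
                      head_units = 2)
  expect_equal(unname(m[4, "x"]), 0)          # tip on the left
  # mirror symmetry about the segment midpoint
  expect_equal(sort(10 - m[, "x"]), sort(p[, "x"]))
  # short gene: head capped at the feature length
  tri <- arrow_geometry(0, 1, y_mid = 5, height = 3, strand = "+",
                        head_units = 2)
  expect_equal(unname(tri[2, "x"]), 0)        # body collapsed
  # clipped edge is flat (4-gon, no head)
  cl <- arrow_geometry(0, 10, y_mid = 5, height = 3, strand = "+",
                       head_units = 2, clip_right = TRUE)
  expect_equal(nrow(cl), 4L)
})

test_that("label visibility implements the comparative-figure rules", {
  fr <- data.frame(
    label = c("portal protein", "portal protein", "hypothetical protein",
              "tail fiber", "integrase"),
    group_id = c("G1", "G1", "G2", "G3", "G4"),
    group_class = c("conserved", "conserved", "variable", "variable",
                    "intermediate"),
    hypothetical = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    show_label = NA,
    row = c(1L, 3L, 1L, 2L, 2L),
    x1 = c(0, 0, 10, 5, 20), stringsAsFactors = FALSE)
  vis <- label_visibility(fr)
  expect_true(vis[1])      # conserved, first occurrence (row 1)
  expect_false(vis[2])     # conserved, repeat occurrence (row 3)
  expect_false(vis[3])     # hypothetical hidden even though variable
  expect_true(vis[4])      # variable shown
  expect_true(vis[5])      # intermediate shown
  # show_label override beats the hypothetical rule
  fr$show_label[3] <- TRUE
  expect_true(label_visibility(fr)[3])
  fr$show_label[1] <- FALSE
  expect_false(label_visibility(fr)[1])
})

test_that("conserved first-occurrence is decided in reading order", {
  fr <- data.frame(label = c("p", "p"), group_id = "G1",
                   group_class = "conserved", hypothetical = FALSE,
                   show_label = NA, row = c(2L, 1L), x1 = c(0, 50),
                   stringsAsFactors = FALSE)
  vis <- label_visibility(fr)
  expect_false(vis[1])  # row 2
  expect_true(vis[2])   # row 1 comes first in reading order despite x
})

test_that("distant labels sit centred on tier 1", {
  labs <- data.frame(text = c("aaa", "bbb"), xc = c(10, 80),
                     feat_w = c(10, 10), width = c(8, 8))
  out <- place_labels(labs, y_tier1 = 5, box_h = 2, x_min = 0, x_max = 100)
  expect_true(all(out$placed))
  expect_true(all(out$tier == 1L))
  expect_equal(out$x1[1], 10 - 4)
  expect_equal(count_label_overlaps(out), 0L)
})

test_that("crowded labels slide or promote but never overlap", {
  labs <- data.frame(text = c("wide label A", "wide label B"),
                     xc = c(50, 53), feat_w = c(6, 6),
                     width = c(20, 20))
  out <- place_labels(labs, y_tier1 = 5, box_h = 2, x_min = 0, x_max = 100)
  expect_true(all(out$placed))
  expect_equal(count_label_overlaps(out), 0L)
  expect_true(any(out$tier == 2L) || all(out$tier == 1L))
})

test_that("pathological crowding drops labels with a warning, zero overlaps", {
  set.seed(1)
  labs <- data.frame(text = sprintf("protein %02d", 1:50),
                     xc = runif(50, 0, 10), feat_w = 0.2,
                     width = runif(50, 3, 6))
  expect_warning(
    out <- place_labels(labs, y_tier1 = 5, box_h = 2, x_min = 0, x_max = 10),
    "dropped")
  expect_true(sum(out$placed) < 50)
  expect_equal(count_label_overlaps(out), 0L)
})

test_that("connectors join equal groups in adjacent rows only", {
  rows <- list(
    data.frame(group_id = c("G1", "G2"), x1 = c(0, 20), x2 = c(10, 30)),
    data.frame(group_id = c("G1"), x1 = 5, x2 = 15),
    data.frame(group_id = c("G1", "G2"), x1 = c(0, 40), x2 = c(10, 50)))
  cn <- homology_connectors(rows, y_bottoms = c(10, 20, 30),
                            y_tops = c(8, 18, 28))
  # G1 joins rows 1-2 and 2-3; G2 present in rows 1 and 3 only -> no link
  expect_equal(nrow(cn), 2L)
  expect_true(all(cn$group_id == "G1"))
  expect_equal(sort(cn$row_top), c(1L, 2L))
})

test_that("paralogue copies connect to the nearest copy by midpoint", {
  rows <- list(
    data.frame(group_id = "G1", x1 = 40, x2 = 50),          # mid 45
    data.frame(group_id = c("G1", "G1"), x1 = c(0, 38), x2 = c(10, 52)))
  cn <- homology_connectors(rows, y_bottoms = c(10, 20), y_tops = c(8, 18))
  expect_equal(nrow(cn), 1L)
  expect_equal(cn$bx1, 38)  # nearer copy (mid 45 vs mid 5)
})

test_that("category strip covers categorized ORFs and builds a legend", {
  feats <- data.frame(category = c("lysis", NA, "tail"),
                      x1 = c(0, 20, 40), x2 = c(10, 30, 55))
  st <- category_strip(feats, y = 12)
  expect_equal(nrow(st$segments), 2L)
  expect_setequal(st$legend$category, c("lysis", "tail"))
  # unknown category falls back to the reserved colour with a warning
  expect_warning(
    st2 <- category_strip(data.frame(category = "martian", x1 = 0, x2 = 5),
                          y = 1), "martian")
  expect_equal(st2$segments$color, unname(lociview:::PHROG_PALETTE[["other"]]))
  # none categorized: no strip, no legend
  st3 <- category_strip(data.frame(category = NA_character_, x1 = 0, x2 = 5),
                        y = 1)
  expect_equal(nrow(st3$segments), 0L)
  expect_equal(nrow(st3$legend), 0L)
})

test_that("scale bar follows the 1-2-5 ladder under the width cap", {
  # 40 kbp across 100 units: 0.0025 u/bp; <= 25 units means <= 10 kbp
  sb <- scale_line(units_per_bp = 100 / 40000, width_units = 100)
  expect_equal(sb$bp, 10000)
  expect_equal(sb$label, "10 kbp")
  # 900 bp across 100 units
  sb2 <- scale_line(units_per_bp = 100 / 900, width_units = 100)
  expect_equal(sb2$bp, 200)
  expect_equal(sb2$label, "200 bp")
  for (span in c(700, 3200, 58000, 140000)) {
    s <- scale_line(units_per_bp = 100 / span, width_units = 100)
    expect_lte(s$units, 25 + 1e-9)
  }
})

test_that("full layout keeps one bp scale across rows and clean labels", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 5, n_core = 8, n_cargo_pool = 6,
                        cargo_per_locus = 2, seed = 13)
  res <- run_comparative(set$genbank, tmpd(), quiet = TRUE)
  lay <- res$layout
  # scale consistency: (delta x)/(delta bp) identical across rows
  upbs <- vapply(lay$rows, function(r)
    (bp_to_x(r$transform, 100) - bp_to_x(r$transform, 0)) / 100, numeric(1))
  expect_true(all(abs(upbs - lay$upb) < 1e-9))
  expect_equal(layout_label_overlaps(lay), 0L)
  # connectors anchor same-group features in adjacent rows
  ids <- vapply(lay$rows, function(r) r$locus_id, character(1))
  for (i in seq_len(nrow(lay$connectors))) {
    cn <- lay$connectors[i, ]
    top <- lay$rows[[cn$row_top]]$extents
    bot <- lay$rows[[cn$row_top + 1]]$extents
    expect_true(cn$group_id %in% top$group_id)
    expect_true(cn$group_id %in% bot$group_id)
  }
})

test_that("compact mode hides strips and axes and adds one scale bar", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 3, n_core = 5, n_cargo_pool = 4,
                        cargo_per_locus = 1, seed = 17, with_categories = TRUE)
  loci <- assign_groups(set$loci, cluster_proteins(do.call(rbind, lapply(
    set$loci, function(l) l$features[, c("feature_id", "protein_seq")]))))
  full <- build_layout(loci, load_profile(), mode = "full")
  compact <- build_layout(loci, load_profile(), mode = "compact")
  expect_true(any(!vapply(full$rows, function(r) is.null(r$strip), logical(1))))
  expect_true(all(vapply(compact$rows, function(r) is.null(r$strip), logical(1))))
  expect_true(all(vapply(compact$rows, function(r) is.null(r$axis), logical(1))))
  expect_null(full$scale_bar)
  expect_false(is.null(compact$scale_bar))
})

test_that("layout construction is deterministic", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 3, n_core = 4, n_cargo_pool = 4,
                        cargo_per_locus = 1, seed = 19)
  l1 <- build_layout(set$loci, load_profile())
  l2 <- build_layout(set$loci, load_profile())
  expect_identical(l1, l2)
})

test_that("browser panels stack strip, genes, GC and signals in order", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 1, n_core = 6, n_cargo_pool = 2,
                        cargo_per_locus = 1, seed = 23)
  loc <- set$loci[[1]]
  sig1 <- tempfile(fileext = ".bedgraph")
  make_signal(sig1, "L01", loc$length_bp,
              peaks = list(c(round(loc$length_bp / 2), 100, 20)), seed = 1)
  sig2 <- tempfile(fileext = ".bedgraph")
  make_signal(sig2, "L01", loc$length_bp,
              peaks = list(c(200, 50, 5)), seed = 2)
  span <- c(0L, loc$length_bp)
  tracks <- list(first = parse_bedgraph(sig1, "L01", span),
                 second = parse_bedgraph(sig2, "L01", span))
  lay <- browser_panel(loc, tracks, load_profile())
  kinds <- vapply(lay$panels, function(p) p$kind, character(1))
  expect_equal(kinds, c("gc_content", "gc_skew", "coverage", "coverage"))
  titles <- vapply(lay$panels, function(p) p$title, character(1))
  expect_equal(titles[3:4], c("first", "second"))
  # panels are stacked downward in order
  tops <- vapply(lay$panels, function(p) p$y_top, numeric(1))
  expect_true(all(diff(tops) > 0))
  # no GC option
  lay2 <- browser_panel(loc, tracks["first"], load_profile(), gc = FALSE)
  expect_equal(vapply(lay2$panels, function(p) p$kind, character(1)),
               "coverage")
  # zero tracks: gene map + GC only
  lay3 <- browser_panel(loc, list(), load_profile())
  expect_equal(length(lay3$panels), 2L)
})

test_that("centred track bars are positive exactly where raw > mean", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 1, n_core = 5, n_cargo_pool = 2,
                        cargo_per_locus = 1, seed = 29)
  loc <- set$loci[[1]]
  lay <- browser_panel(loc, list(), load_profile())
  skew <- lay$panels[[which(vapply(lay$panels, function(p) p$kind,
                                   character(1)) == "gc_skew")]]
  # recompute the raw smoothed series independently of the layout
  raw <- gc_skew_track(loc$sequence, loc$locus_id, 1)
  sm <- smooth_adaptive(raw, lay$rows[[1]]$transform$width, 2)
  expect_equal(length(sm$values), nrow(skew$bars))
  expect_equal(skew$bars$positive, sm$values > mean(raw$values) +
                 (mean(sm$values) - mean(raw$values)))
  expect_equal(skew$bars$positive, sm$values - mean(sm$values) > 0)
})

test_that("browser mode rejects multi-locus input", {
  d <- tmpd()
  set <- make_locus_set(d, n_loci = 2, n_core = 3, n_cargo_pool = 2,
                        cargo_per_locus = 1, seed = 31)
  expect_error(browser_panel(set$loci, list(), load_profile()),
               "comparative")
})
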