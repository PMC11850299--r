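# Configuration profiles. Layered resolution: built-in defaults <- named
# profile <- user config file <- explicit overrides. Config files use a flat
# key = value dialect; [section] headers are allowed and ignored (cosmetic
# grouping). Every tunable named in the package documentation is reachable
# here, and a test enumerates them.

lv_default_config <- function() {
  list(
    # page / canvas (canvas units are mm)
    profile = "standard",
    width_units = 160,
    margin_units = 8,
    row_height = 11,
    gene_height = 3.2,
    head_units = 1.6,
    region_gap_units = 2,
    label_fontsize = 6,
    annotation_fontsize = 5,
    mode = "full",                  # full | compact | browser
    # homology clustering
    min_identity = 0.35,
    min_coverage = 0.7,
    # proteome analysis
    similarity = "mean_directional",  # or jaccard
    cluster_cut = 0.75,
    conserved_cutoff = 0.75,
    variable_cutoff = 0.25,
    # signal tracks
    points_per_unit = 2,
    gc_window = 1,
    track_height = 10,
    # layout
    scalebar_fraction = 0.25,
    hypothetical_patterns = DEFAULT_HYPOTHETICAL_PATTERNS,
    # colours
    highlight = "variable",         # variable | conserved
    color_intermediate = TRUE,      # colour intermediate groups too
    palette_seed = 1,
    conserved_color = "#B4B4B4",
    connector_color = "#D8D8D8",
    positive_color = "#2166AC",
    negative_color = "#B2182B",
    signal_color = "#8B1A1A",
    category_palette = PHROG_PALETTE,
    # rendering
    timestamp = "D:20240101000000Z"
  )
}

lv_profiles <- function() {
  list(
    standard = list(width_units = 160),
    # A4 single-column figure width (text block of a one-column page)
    A4p1 = list(width_units = 180),
    # A4 two-column figure width
    A4p2 = list(width_units = 85, label_fontsize = 5, row_height = 9)
  )
}

#' Load a style/parameter profile
#'
#' `name_or_path` is one of the built-in profiles (`"standard"`, `"A4p1"`,
#' `"A4p2"`) or a path to a `key = value` config file (`[section]` headers
#' allowed). Explicit `overrides` win over the profile, which wins over the
#' defaults. Unknown keys raise an error listing the valid ones.
#'
#' @param name_or_path profile name or config file path
#' @param overrides named list of final overrides (e.g. from CLI flags)
#' @return a complete configuration list (class `lv_config`)
#' @export
load_profile <- function(name_or_path = "standard", overrides = list()) {
  cfg <- lv_default_config()
  profiles <- lv_profiles()
  if (name_or_path %in% names(profiles)) {
    layer <- profiles[[name_or_path]]
    layer$profile <- name_or_path
  } else if (file.exists(name_or_path)) {
    layer <- parse_config_file(name_or_path)
    layer$profile <- name_or_path
  } else {
    stop2("unknown profile '", name_or_path, "'; built-in profiles: ",
          paste(names(profiles), collapse = ", "),
          " (or pass a config file path)")
  }
  cfg <- merge_config(cfg, layer)
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "lv_config")
}

merge_config <- function(cfg, layer) {
  if (!length(layer)) return(cfg)
  bad <- setdiff(names(layer), names(lv_default_config()))
  if (length(bad))
    stop2("unknown configuration key(s): ", paste(bad, collapse = ", "),
          "\nvalid keys: ", paste(names(lv_default_config()), collapse = ", "))
  for (k in names(layer)) cfg[[k]] <- layer[[k]]
  cfg
}

# key = value parser; values are coerced to logical/numeric when they look
# like one, comma-separated values become vectors
parse_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in lines) {
    txt <- trimws(ln)
    # full-line comments only: values may legitimately contain '#' (colours)
    if (!nzchar(txt) || grepl("^[#;\\[]", txt)) next
    eq <- regexpr("=", txt, fixed = TRUE)
    if (eq == -1L) stop2(path, ": malformed config line: '", ln, "'")
    key <- trimws(substring(txt, 1L, eq - 1L))
    val <- trimws(substring(txt, eq + 1L))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    conv <- function(v) {
      if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(toupper(v)))
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }
    vals <- lapply(parts, conv)
    out[[key]] <- if (length(vals) == 1L) vals[[1]] else unlist(vals)
  }
  out
}
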