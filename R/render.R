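#' Fingerprint figure style
#'
#' @param colormap Name of a diverging palette: `"orange_blue"`
#'   (default; negative values blue, positive orange, white at zero),
#'   `"red_blue"`, or `"viridis"` for non-negative data.
#' @param color_limits `"auto"` (symmetric about 0 when the data span
#'   both signs, `[0, max]` for non-negative data) or a numeric pair.
#' @param cell_size Cell edge in pixels.
#' @param separator_width Gap between gross-region groups, pixels; the
#'   hemisphere gap is three times this.
#' @param label_font_size Font size for labels, pixels.
#' @param missing_cell_style Fill colour for missing cells (drawn with
#'   a diagonal slash).
#' @return A list of class `brainglance_style`.
#' @export
brainglance_style <- function(colormap = "orange_blue", color_limits = "auto",
                              cell_size = 14, separator_width = 6,
                              label_font_size = 9,
                              missing_cell_style = "#BDBDBD") {
  if (is.numeric(color_limits)) {
    if (length(color_limits) != 2L || color_limits[1] >= color_limits[2]) {
      stop("Numeric `color_limits` must be an increasing pair.", call. = FALSE)
    }
  } else if (!identical(color_limits, "auto")) {
    stop("`color_limits` must be \"auto\" or a numeric pair.", call. = FALSE)
  }
  structure(list(colormap = colormap, color_limits = color_limits,
                 cell_size = cell_size, separator_width = separator_width,
                 label_font_size = label_font_size,
                 missing_cell_style = missing_cell_style),
            class = "brainglance_style")
}

palette_stops <- function(colormap) {
  switch(colormap,
         orange_blue = c("#2166AC", "#F7F7F7", "#E08214"),
         red_blue = c("#2166AC", "#F7F7F7", "#B2182B"),
         viridis = grDevices::hcl.colors(11, "viridis"),
         stop("Unknown colormap '", colormap, "'.", call. = FALSE))
}

#' Resolve colour limits for a set of values
#'
#' @param values Numeric vector (NA allowed).
#' @param style A [brainglance_style()].
#' @return Numeric pair `c(lo, hi)`.
#' @export
resolve_color_limits <- function(values, style) {
  if (is.numeric(style$color_limits)) return(style$color_limits)
  v <- values[is.finite(values)]
  if (!length(v)) return(c(-1, 1))
  if (min(v) < 0 && max(v) > 0) {
    m <- max(abs(v))
    c(-m, m)
  } else if (min(v) >= 0) {
    c(0, max(v, .Machine$double.eps))
  } else {
    c(min(v), 0)
  }
}

#' Map values to colours
#'
#' Linear mapping of each value to a position in `[0, 1]` between the
#' resolved colour limits (clipping outside), then interpolation
#' along the palette. Missing values get the missing-cell colour.
#' The mapping is global over the values passed in, never
#' per-region, so shades are comparable across the whole figure.
#'
#' @param values Numeric vector.
#' @param style A [brainglance_style()].
#' @param limits Optional pre-resolved limits (numeric pair).
#' @return Character vector of hex colours.
#' @export
map_colors <- function(values, style = brainglance_style(), limits = NULL) {
  if (is.null(limits)) limits <- resolve_color_limits(values, style)
  pos <- (values - limits[1]) / (limits[2] - limits[1])
  pos <- pmin(pmax(pos, 0), 1)
  ramp <- grDevices::colorRamp(palette_stops(style$colormap), space = "Lab")
  out <- rep(style$missing_cell_style, length(values))
  ok <- is.finite(pos)
  if (any(ok)) {
    rgbm <- ramp(pos[ok])
    out[ok] <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3], maxColorValue = 255)
  }
  out
}

#' Row heights for cluster bands
#'
#' A cluster of size `s` is drawn `1 + log10(s)` row units tall, so a
#' singleton stays exactly one unit and a tenfold larger group gains
#' one unit — sizes remain visible without letting a dominant cluster
#' swallow the figure.
#'
#' @param sizes Positive integer group sizes.
#' @return Numeric heights in row units.
#' @export
compute_row_heights <- function(sizes) {
  if (any(!is.finite(sizes)) || any(sizes < 1) || any(sizes != round(sizes))) {
    stop("`sizes` must be integers >= 1.", call. = FALSE)
  }
  1 + log10(sizes)
}

#' Geometry of a fingerprint figure
#'
#' Computes the full cell layout (positions, sizes, colours) of a
#' fingerprint before anything is drawn, so the structure can be
#' inspected and asserted independently of any graphics device.
#'
#' @param matrix A [region_matrix] (subject- or cluster-level).
#' @param layout A [build_column_layout()] result.
#' @param style A [brainglance_style()].
#' @return A list of class `brainglance_geometry`: `cells` tibble
#'   (`row`, `col`, `label`, `subject_id`, `value`, `color`, `x`,
#'   `y`, `w`, `h`), `columns`, `row_heights`, `limits`, `width`,
#'   `height`, plus label/separator tables.
#' @export
brainglance_geometry <- function(matrix, layout, style = brainglance_style()) {
  stopifnot(inherits(matrix, "region_matrix"), inherits(layout, "column_layout"))
  m_labels <- attr(matrix, "region_labels")
  unknown <- setdiff(m_labels, layout$label)
  if (length(unknown)) {
    stop("Region label(s) in matrix but not in layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  X <- unclass(matrix)
  row_of <- match(layout$label, m_labels)   # NA -> column absent from matrix
  subj <- attr(matrix, "subject_ids")
  sizes <- attr(matrix, "sizes")
  heights <- if (is.null(sizes)) rep(1, ncol(X)) else compute_row_heights(sizes)

  cs <- style$cell_size
  sep <- style$separator_width
  gb <- attr(layout, "group_boundaries")
  split_at <- attr(layout, "hemisphere_split")
  # x offset per column: group separators, wider gap at the hemisphere split
  xgap <- numeric(nrow(layout))
  for (i in seq_len(nrow(layout))[-1]) {
    xgap[i] <- xgap[i - 1] +
      (if (i %in% gb) sep else 0) +
      (if (i == split_at + 1L) 2 * sep else 0)
  }
  margin_left <- 90
  margin_top <- 70
  x0 <- margin_left + (seq_len(nrow(layout)) - 1) * cs + xgap
  y0 <- margin_top + c(0, cumsum(heights[-length(heights)])) * cs

  vals <- X[row_of, , drop = FALSE]          # columns-of-figure x subjects
  limits <- resolve_color_limits(as.vector(X), style)
  cells <- tibble::tibble(
    row = rep(seq_along(subj), each = nrow(layout)),
    col = rep(seq_len(nrow(layout)), times = length(subj)),
    label = rep(layout$label, times = length(subj)),
    subject_id = rep(subj, each = nrow(layout)),
    value = as.vector(vals),
    x = rep(x0, times = length(subj)),
    y = rep(y0, each = nrow(layout)),
    w = cs,
    h = rep(heights * cs, each = nrow(layout))
  )
  cells$color <- map_colors(cells$value, style, limits)

  groups <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(x = x0,
                                   grp = paste(layout$hemisphere,
                                               layout$name_largescale_region)),
                    .data$grp),
    x_mid = (min(.data$x) + max(.data$x) + cs) / 2, .groups = "drop")

  structure(list(
    cells = cells,
    columns = layout,
    row_heights = heights,
    limits = limits,
    col_x = x0, row_y = y0,
    group_labels = groups,
    margin_left = margin_left, margin_top = margin_top,
    width = max(x0) + cs + 70,
    height = max(y0) + heights[length(heights)] * cs + 60,
    style = style
  ), class = "brainglance_geometry")
}

svg_num <- function(x) formatC(x, digits = 2, format = "f")

svg_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# deterministic SVG: fixed element order, fixed number formatting, no ids
write_fingerprint_svg <- function(geom, path) {
  st <- geom$style
  fs <- st$label_font_size
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            svg_num(geom$width), svg_num(geom$height),
            svg_num(geom$width), svg_num(geom$height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
            svg_num(geom$width), svg_num(geom$height))
  )
  cells <- geom$cells
  miss <- is.na(cells$value)
  lines <- c(lines, sprintf(
    '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
    svg_num(cells$x), svg_num(cells$y), svg_num(cells$w - 1),
    svg_num(cells$h - 1), cells$color))
  if (any(miss)) {  # slash marks a region absent from the subject's atlas
    mc <- cells[miss, ]
    lines <- c(lines, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#FFFFFF" stroke-width="1"/>',
      svg_num(mc$x), svg_num(mc$y + mc$h - 1), svg_num(mc$x + mc$w - 1), svg_num(mc$y)))
  }
  # column labels, rotated, above the grid
  lines <- c(lines, sprintf(
    '<text x="%s" y="%s" font-size="%s" font-family="sans-serif" text-anchor="start" transform="rotate(-60 %s %s)">%s</text>',
    svg_num(geom$col_x + st$cell_size / 2), svg_num(geom$margin_top - 6),
    svg_num(fs), svg_num(geom$col_x + st$cell_size / 2),
    svg_num(geom$margin_top - 6), svg_escape(geom$columns$name_area)))
  # gross-region labels (e.g. "L INS", "R INS")
  lines <- c(lines, sprintf(
    '<text x="%s" y="%s" font-size="%s" font-family="sans-serif" font-weight="bold" text-anchor="middle">%s</text>',
    svg_num(geom$group_labels$x_mid), svg_num(12 + fs),
    svg_num(fs + 1), svg_escape(geom$group_labels$grp)))
  # row labels
  subj <- unique(geom$cells[, c("row", "subject_id", "y", "h")])
  lines <- c(lines, sprintf(
    '<text x="%s" y="%s" font-size="%s" font-family="sans-serif" text-anchor="end">%s</text>',
    svg_num(geom$margin_left - 6), svg_num(subj$y + subj$h / 2 + fs / 3),
    svg_num(fs), svg_escape(subj$subject_id)))
  # colorbar: 32 bands + end labels
  bar_x <- geom$width - 50
  bar_h <- min(140, geom$height - geom$margin_top - 20)
  bar_y <- geom$margin_top
  nb <- 32L
  bv <- seq(geom$limits[2], geom$limits[1], length.out = nb)
  bcol <- map_colors(bv, st, geom$limits)
  lines <- c(lines, sprintf(
    '<rect x="%s" y="%s" width="12" height="%s" fill="%s"/>',
    svg_num(bar_x), svg_num(bar_y + (seq_len(nb) - 1) * bar_h / nb),
    svg_num(bar_h / nb + 0.5), bcol))
  lines <- c(lines, sprintf(
    '<text x="%s" y="%s" font-size="%s" font-family="sans-serif">%s</text>',
    svg_num(bar_x + 16), svg_num(c(bar_y + fs / 2, bar_y + bar_h)),
    svg_num(fs), svg_escape(formatC(geom$limits[c(2, 1)], digits = 3, format = "g"))))
  lines <- c(lines, "</svg>")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Draw the fingerprint figure
#'
#' One coloured square per (subject or cluster, brain area): rows are
#' subjects (cluster rows scaled by [compute_row_heights()]), columns
#' follow the mirror-symmetric [build_column_layout()] with a wider
#' central gap between hemispheres and thin gaps between gross-region
#' groups, labelled like `L INS` / `R INS`. Missing cells are grey
#' with a slash. `.svg` output is written by the package's own
#' deterministic emitter (byte-identical across repeat renders, hence
#' diffable); `.png` and `.pdf` go through the [autoplot()] ggplot.
#'
#' @param matrix A [region_matrix].
#' @param layout A [build_column_layout()] result covering the
#'   matrix's regions.
#' @param style A [brainglance_style()].
#' @param output_path Destination file; format from extension.
#' @return The [brainglance_geometry()] used, invisibly.
#' @export
render_brainglance <- function(matrix, layout, style = brainglance_style(),
                               output_path) {
  geom <- brainglance_geometry(matrix, layout, style)
  stopifnot(length(unique(geom$cells$col)) == nrow(layout))
  ext <- tolower(tools::file_ext(output_path))
  dir <- dirname(output_path)
  if (!dir.exists(dir)) {
    stop("Output directory does not exist: ", dir, call. = FALSE)
  }
  if (ext == "svg") {
    write_fingerprint_svg(geom, output_path)
  } else if (ext %in% c("png", "pdf")) {
    p <- autoplot(matrix, layout = layout, style = style)
    ggplot2::ggsave(output_path, p,
                    width = max(4, geom$width / 72),
                    height = max(3, geom$height / 72), dpi = 150,
                    limitsize = FALSE)
  } else {
    stop("Unsupported figure format '.", ext, "'; use .svg, .png or .pdf.",
         call. = FALSE)
  }
  invisible(geom)
}

#' ggplot of a region matrix fingerprint
#'
#' @param object A [region_matrix].
#' @param layout Optional [build_column_layout()]; without it, columns
#'   follow matrix row order.
#' @param style A [brainglance_style()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot region_matrix
#' @export
autoplot.region_matrix <- function(object, layout = NULL,
                                   style = brainglance_style(), ...) {
  long <- tidy(object)
  if (!is.null(layout)) {
    long$name_area <- factor(
      paste(long$label, long$name_area),
      levels = paste(layout$label, layout$name_area))
    long <- long[!is.na(long$name_area), ]
  } else {
    long$name_area <- factor(paste(long$label, long$name_area),
                             levels = unique(paste(long$label, long$name_area)))
  }
  long$subject_id <- factor(long$subject_id,
                            levels = rev(attr(object, "subject_ids")))
  limits <- resolve_color_limits(as.vector(object), style)
  stops <- palette_stops(style$colormap)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name_area, y = .data$subject_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.3) +
    ggplot2::scale_fill_gradientn(colours = stops, limits = limits,
                                  na.value = style$missing_cell_style) +
    ggplot2::labs(x = NULL, y = NULL, fill = attr(object, "statistic")) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Two-panel rendering of a native-vs-template comparison
#'
#' Upper band: per-region mean difference (native minus template).
#' Lower band: the t statistic, shown only where significant at the
#' comparison's alpha (non-significant regions are blanked), the
#' standard thresholded-statistics view.
#'
#' @param comparison A `region_comparison` from [ttest_per_region()].
#' @param layout A [build_column_layout()].
#' @param style A [brainglance_style()].
#' @param output_path Destination (`.svg`, `.png`, `.pdf`).
#' @return The geometry used, invisibly.
#' @export
render_comparison <- function(comparison, layout, style = brainglance_style(),
                              output_path) {
  stopifnot(inherits(comparison, "region_comparison"))
  t_thr <- ifelse(comparison$significant, comparison$t_statistic, NA_real_)
  M <- rbind(comparison$mean_difference, t_thr)
  two <- new_region_matrix(t(M), comparison$label, comparison$name_area,
                           c("mean difference",
                             paste0("t (p<", attr(comparison, "alpha"), ")")),
                           "comparison")
  render_brainglance(two, layout, style, output_path)
}
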