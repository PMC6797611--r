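insula_fixture <- function(n_subjects = 4L, seed = 71L) {
  def <- atlas_definition(data.frame(
    label = 1:12,
    name_area = rep(paste0("INS_6_", 1:6), 2),
    name_largescale_region = "INS",
    hemisphere = rep(c("L", "R"), each = 6)))
  set.seed(seed)
  X <- matrix(rnorm(12 * n_subjects), 12, n_subjects)
  S <- rm_from_matrix(X)
  attr(S, "region_labels") <- def$label
  attr(S, "region_names") <- def$name_area
  list(def = def, layout = build_column_layout(def), S = S)
}

test_that("row heights follow the anchored log rule", {
  expect_equal(compute_row_heights(1L), 1)
  expect_equal(compute_row_heights(c(1L, 10L, 100L)), c(1, 2, 3))
  heights <- compute_row_heights(1:1000)
  expect_true(all(diff(heights) > 0))
  expect_error(compute_row_heights(0L), ">= 1")
  expect_error(compute_row_heights(2.5), ">= 1")
})

test_that("colour mapping is the clipped affine transform into the palette", {
  style <- brainglance_style(color_limits = c(-2, 2))
  mid <- map_colors(0, style)
  expect_equal(mid, map_colors(0, brainglance_style(color_limits = c(-5, 5))))
  ends <- map_colors(c(-2, 2), style)
  expect_equal(ends, map_colors(c(-99, 99), style))   # clipping
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#E08214"), space = "Lab")
  set.seed(72)
  v <- runif(20, -2, 2)
  want <- grDevices::rgb(ramp((v + 2) / 4), maxColorValue = 255)
  expect_equal(map_colors(v, style), want)
  expect_equal(map_colors(NA_real_, style), style$missing_cell_style)
})

test_that("auto colour limits are symmetric for signed, anchored for one-signed data", {
  st <- brainglance_style()
  expect_equal(resolve_color_limits(c(-1, 3), st), c(-3, 3))
  expect_equal(resolve_color_limits(c(0.5, 2), st), c(0, 2))
  expect_equal(resolve_color_limits(c(-4, -1), st), c(-4, 0))
})

test_that("colour position is monotone in the value", {
  # on a sequential palette, perceptual lightness must track the value
  style <- brainglance_style(colormap = "viridis", color_limits = c(0, 1))
  v <- seq(0, 1, length.out = 50)
  cols <- map_colors(v, style)
  lab <- grDevices::convertColor(t(grDevices::col2rgb(cols)) / 255,
                                 from = "sRGB", to = "Lab")
  expect_true(all(diff(lab[, 1]) > 0))
  # and equal values always map to equal colours
  expect_equal(map_colors(c(0.3, 0.3), style),
               rep(map_colors(0.3, style), 2))
})

test_that("the four-subject insula figure reproduces the canonical structure", {
  fx <- insula_fixture()
  geom <- brainglance_geometry(fx$S, fx$layout)
  expect_equal(length(unique(geom$cells$col)), 12L)
  expect_equal(length(unique(geom$cells$row)), 4L)
  expect_equal(nrow(geom$cells), 48L)
  expect_equal(sum(geom$row_heights), 4)
  # central separator: the gap between columns 6 and 7 is wider than
  # between any within-hemisphere pair
  gaps <- diff(geom$col_x)
  expect_gt(gaps[6], max(gaps[-6]))
  expect_setequal(geom$group_labels$grp, c("L INS", "R INS"))
})

test_that("one mirrored pair renders as a 1x2 grid with a central gap", {
  def <- atlas_definition(data.frame(
    label = 1:2, name_area = "a", name_largescale_region = "FRO",
    hemisphere = c("L", "R")))
  S <- rm_from_matrix(matrix(c(1, -1), 2, 1))
  attr(S, "region_labels") <- def$label
  attr(S, "region_names") <- def$name_area
  geom <- brainglance_geometry(S, build_column_layout(def))
  expect_equal(nrow(geom$cells), 2L)
  st <- brainglance_style()
  expect_gt(diff(geom$col_x), st$cell_size)   # separator present
})

test_that("grid geometry totals match the matrix and heights", {
  px_sizes <- c(20L, 5L, 1L)
  set.seed(73)
  S <- rm_from_matrix(matrix(rnorm(18), 6, 3))
  attr(S, "sizes") <- px_sizes
  def <- suppressWarnings(atlas_definition(data.frame(
    label = 1:6, name_area = paste0("a", 1:6),
    name_largescale_region = "G1", hemisphere = rep(c("L", "R"), 3))))
  lay <- suppressWarnings(build_column_layout(def))
  geom <- brainglance_geometry(S, lay)
  expect_equal(length(unique(geom$cells$col)), nrow(def))
  expect_equal(sum(geom$row_heights), sum(1 + log10(px_sizes)))
  hts <- unique(geom$cells[, c("row", "h")])
  expect_equal(hts$h, compute_row_heights(px_sizes) * brainglance_style()$cell_size)
})

test_that("repeat SVG renders are byte-identical; unknown regions refused", {
  fx <- insula_fixture()
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_brainglance(fx$S, fx$layout, output_path = f1)
  render_brainglance(fx$S, fx$layout, output_path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  svg <- readLines(f1)
  expect_match(svg[2], "^<svg xmlns")
  expect_length(grep("INS_6_", svg), 12L)

  bad <- fx$S
  attr(bad, "region_labels") <- c(1:11, 99L)
  expect_error(render_brainglance(bad, fx$layout, output_path = f1), "99")
  expect_error(render_brainglance(fx$S, fx$layout,
                                  output_path = "/nonexistent/dir/x.svg"),
               "directory")
  expect_error(render_brainglance(fx$S, fx$layout,
                                  output_path = withr::local_tempfile(fileext = ".bmp")),
               "Unsupported")
})

test_that("missing cells are drawn in the missing style", {
  fx <- insula_fixture(n_subjects = 2L)
  M <- unclass(fx$S)
  M[3, 1] <- NA
  S <- brainglance:::new_region_matrix(M, attr(fx$S, "region_labels"),
                                       attr(fx$S, "region_names"),
                                       attr(fx$S, "subject_ids"), "mean")
  geom <- brainglance_geometry(S, fx$layout)
  st <- brainglance_style()
  miss <- geom$cells[is.na(geom$cells$value), ]
  expect_equal(nrow(miss), 1L)
  expect_equal(miss$color, st$missing_cell_style)
  f <- withr::local_tempfile(fileext = ".svg")
  render_brainglance(S, fx$layout, output_path = f)
  expect_length(grep(st$missing_cell_style, readLines(f)), 1L)
})

test_that("autoplot returns a tile plot and png rendering writes a file", {
  fx <- insula_fixture()
  p <- autoplot(fx$S, layout = fx$layout)
  expect_s3_class(p, "ggplot")
  expect_true(any(vapply(p$layers, function(l) inherits(l$geom, "GeomTile"),
                         logical(1))))
  f <- withr::local_tempfile(fileext = ".png")
  render_brainglance(fx$S, fx$layout, output_path = f)
  expect_gt(file.size(f), 1000)
})

test_that("comparison rendering produces the two-panel figure", {
  fx <- insula_fixture(n_subjects = 8L)
  set.seed(74)
  tpl <- rm_from_matrix(unclass(fx$S) + matrix(rnorm(96, 0.5, 0.2), 12, 8))
  attr(tpl, "region_labels") <- attr(fx$S, "region_labels")
  attr(tpl, "region_names") <- attr(fx$S, "region_names")
  attr(tpl, "subject_ids") <- attr(fx$S, "subject_ids")
  cmp <- ttest_per_region(region_differences(fx$S, tpl))
  f <- withr::local_tempfile(fileext = ".svg")
  geom <- render_comparison(cmp, fx$layout, output_path = f)
  expect_equal(length(unique(geom$cells$row)), 2L)
  expect_equal(length(unique(geom$cells$col)), 12L)
  expect_true(file.size(f) > 0)
})
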