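#' Build an atlas definition from a data frame
#'
#' The atlas definition is the catalogue that maps every integer label
#' occurring in a parcellation volume to a displayable brain area: its
#' short name (e.g. `INS_6_1`), its gross anatomical group used for
#' column grouping (e.g. `FRO`, `INS`, `TEM`), and its hemisphere.
#' Hemisphere strings are upper-cased before validation and must then
#' be exactly `"L"` or `"R"` — the display layout is strictly
#' two-sided. Row order is preserved: it defines the within-group
#' column order of the fingerprint.
#'
#' @param areas Data frame with columns `label`, `name_area`,
#'   `name_largescale_region`, `hemisphere` (one row per area).
#' @return A tibble of class `atlas_definition` with normalized
#'   columns; `nrow()` is the number of areas M.
#' @examples
#' atlas_definition(data.frame(
#'   label = 1:4, name_area = c("a1", "a2", "a1", "a2"),
#'   name_largescale_region = "FRO", hemisphere = c("L", "L", "R", "R")))
#' @export
atlas_definition <- function(areas) {
  areas <- tibble::as_tibble(areas)
  needed <- c("label", "name_area", "name_largescale_region", "hemisphere")
  missing_cols <- setdiff(needed, names(areas))
  if (length(missing_cols)) {
    stop("Atlas definition is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(areas) < 1L) {
    stop("Atlas definition must contain at least one area.", call. = FALSE)
  }
  def <- tibble::tibble(
    label = suppressWarnings(as.integer(areas$label)),
    name_area = trimws(as.character(areas$name_area)),
    name_largescale_region = toupper(trimws(as.character(areas$name_largescale_region))),
    hemisphere = toupper(trimws(as.character(areas$hemisphere)))
  )
  if (any(is.na(def$label)) || any(def$label < 1L)) {
    stop("Area labels must be positive integers.", call. = FALSE)
  }
  dup <- def$label[duplicated(def$label)]
  if (length(dup)) {
    stop("Duplicate atlas label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(def$label == 0L)) {
    stop("Label 0 is reserved for background and cannot define an area.",
         call. = FALSE)
  }
  bad_hemi <- setdiff(unique(def$hemisphere), c("L", "R"))
  if (length(bad_hemi)) {
    stop("Hemisphere must be 'L' or 'R' (after upper-casing); got: ",
         paste(bad_hemi, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(def$name_area))) {
    stop("Every area needs a non-empty name_area.", call. = FALSE)
  }
  # areas whose (gross region, name) tuple exists in only one hemisphere
  # cannot be mirrored; report, don't fail
  key <- paste(def$name_largescale_region, def$name_area, sep = "\r")
  l_keys <- key[def$hemisphere == "L"]
  r_keys <- key[def$hemisphere == "R"]
  unpaired <- def[(def$hemisphere == "L" & !(key %in% r_keys)) |
                    (def$hemisphere == "R" & !(key %in% l_keys)), ]
  if (nrow(unpaired)) {
    warning("Area(s) without a contralateral partner (placed at the outer ",
            "edge of their hemisphere in the display): ",
            paste(unpaired$hemisphere, unpaired$name_area, collapse = ", "),
            call. = FALSE)
  }
  class(def) <- c("atlas_definition", class(def))
  def
}

#' Read a tab-delimited atlas description
#'
#' Parses the plain-text table that usually ships with a volumetric
#' atlas (one row per area). The dialect follows common practice:
#' tab-delimited, `#` starts a comment line, an optional single header
#' row can be skipped, and the meaning of each column is supplied
#' through `column_map` so arbitrary atlas file layouts can be read
#' without reformatting.
#'
#' @param path Path to the text file (or a literal string containing
#'   the table if `text` is used instead of `path`).
#' @param column_map Named integer vector giving, for each of the
#'   semantic fields `label`, `name_area`, `name_largescale_region`,
#'   `hemisphere`, the 1-based column index holding it.
#' @param header Logical; skip one header row before the data rows.
#' @param sep Field separator, default tab.
#' @param text Optional literal table text (overrides `path`).
#' @return An [atlas_definition()].
#' @export
read_atlas_description <- function(path = NULL,
                                   column_map = c(label = 1L, name_area = 2L,
                                                  name_largescale_region = 3L,
                                                  hemisphere = 4L),
                                   header = FALSE, sep = "\t", text = NULL) {
  needed <- c("label", "name_area", "name_largescale_region", "hemisphere")
  if (!all(needed %in% names(column_map))) {
    stop("`column_map` must name all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  args <- list(sep = sep, comment.char = "#", header = FALSE,
               colClasses = "character", stringsAsFactors = FALSE,
               blank.lines.skip = TRUE, quote = "")
  tab <- tryCatch(
    if (is.null(text)) do.call(utils::read.table, c(list(file = path), args))
    else do.call(utils::read.table, c(list(text = text), args)),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        stop("Atlas description has no data rows.", call. = FALSE)
      }
      stop("Could not parse atlas description: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (header) {
    if (nrow(tab) < 2L) stop("Atlas description has no data rows.", call. = FALSE)
    tab <- tab[-1L, , drop = FALSE]
  }
  if (nrow(tab) < 1L) stop("Atlas description has no data rows.", call. = FALSE)
  idx <- as.integer(column_map[needed])
  if (any(idx < 1L) || any(idx > ncol(tab))) {
    stop("`column_map` addresses column(s) outside the table (table has ",
         ncol(tab), " columns).", call. = FALSE)
  }
  atlas_definition(stats::setNames(tab[, idx, drop = FALSE], needed))
}

#' Serialize an atlas definition back to tab-delimited text
#'
#' Inverse of [read_atlas_description()] with the default column map:
#' `read_atlas_description(write_atlas_description(def, f))` is the
#' identity.
#'
#' @param definition An [atlas_definition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas_description <- function(definition, path) {
  stopifnot(inherits(definition, "atlas_definition"))
  utils::write.table(as.data.frame(definition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Check a label volume against an atlas definition
#'
#' Warped atlases should be checked before use: nearest-neighbour
#' warping can drop small areas entirely (these become missing values
#' in the region matrix) and a wrong file may carry labels the
#' definition does not know. The report lists both, plus the voxel
#' count per defined label.
#'
#' @param vol A [label_volume()].
#' @param definition An [atlas_definition()].
#' @return A list of class `label_validation` with elements
#'   `counts` (tibble: label, name_area, n_voxels), `unknown_labels`
#'   (integer labels in the volume absent from the definition),
#'   `empty_labels` (defined labels with zero voxels) and `ok`.
#' @export
validate_label_volume <- function(vol, definition) {
  stopifnot(inherits(vol, "label_volume"), inherits(definition, "atlas_definition"))
  present <- table(vol$grid[vol$grid > 0L])
  present_labels <- as.integer(names(present))
  counts <- tibble::tibble(
    label = definition$label,
    name_area = definition$name_area,
    n_voxels = as.integer(present[as.character(definition$label)])
  )
  counts$n_voxels[is.na(counts$n_voxels)] <- 0L
  res <- structure(
    list(counts = counts,
         unknown_labels = setdiff(present_labels, definition$label),
         empty_labels = counts$label[counts$n_voxels == 0L]),
    class = "label_validation"
  )
  res$ok <- length(res$unknown_labels) == 0L && length(res$empty_labels) == 0L
  res
}

#' @export
print.label_validation <- function(x, ...) {
  cat("Label volume validation:", if (x$ok) "OK" else "ISSUES FOUND", "\n")
  if (length(x$unknown_labels)) {
    cat("  labels in volume but not in definition: ",
        paste(x$unknown_labels, collapse = ", "), "\n", sep = "")
  }
  if (length(x$empty_labels)) {
    cat("  defined labels with zero voxels (missing downstream): ",
        paste(x$empty_labels, collapse = ", "), "\n", sep = "")
  }
  cat("  voxels per defined label: min ", min(x$counts$n_voxels),
      ", median ", stats::median(x$counts$n_voxels),
      ", max ", max(x$counts$n_voxels), "\n", sep = "")
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param x A `label_validation` report.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
validation_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "label_validation"))
  js <- jsonlite::toJSON(
    list(ok = x$ok, unknown_labels = x$unknown_labels,
         empty_labels = x$empty_labels, counts = x$counts),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Mirror-symmetric display column ordering
#'
#' Orders the M atlas areas into the fingerprint's columns: the left
#' hemisphere fills the left half (gross-region groups in definition
#' order of first appearance, areas within a group in definition
#' order); the right half mirrors it, reversing both the group order
#' and the within-group order, so that the innermost column of each
#' half shows the same (gross region, area) pair. Areas with no
#' contralateral partner are kept and pushed to the outer edge of
#' their half, with a warning.
#'
#' @param definition An [atlas_definition()].
#' @return A tibble of class `column_layout` with columns `position`,
#'   `label`, `name_area`, `name_largescale_region`, `hemisphere`, and
#'   attributes `group_boundaries` (1-based start index of every
#'   gross-region group, per hemisphere) and `hemisphere_split` (index
#'   of the last left-half column).
#' @export
build_column_layout <- function(definition) {
  stopifnot(inherits(definition, "atlas_definition"))
  def <- tibble::as_tibble(definition)
  key <- paste(def$name_largescale_region, def$name_area, sep = "\r")
  l <- def[def$hemisphere == "L", ]
  r <- def[def$hemisphere == "R", ]
  lk <- key[def$hemisphere == "L"]
  rk <- key[def$hemisphere == "R"]
  l_paired <- lk %in% rk
  r_paired <- rk %in% lk
  if (any(!l_paired) || any(!r_paired)) {
    warning("Unmirrored area(s) placed at the outer edge of their half: ",
            paste(c(paste("L", l$name_area[!l_paired]),
                    paste("R", r$name_area[!r_paired])), collapse = ", "),
            call. = FALSE)
  }
  # left half: unpaired L areas at the far left (outer edge), then the
  # paired areas in definition order; the right half mirrors the paired
  # sequence about the centre and pushes unpaired R areas to the far
  # right (its outer edge)
  left <- rbind(l[!l_paired, ], l[l_paired, ])
  right_outer_first <- rbind(r[!r_paired, ], r[r_paired, ])
  right <- right_outer_first[rev(seq_len(nrow(right_outer_first))), ]
  cols <- rbind(left, right)
  layout <- tibble::tibble(position = seq_len(nrow(cols)), cols)
  grp <- layout$name_largescale_region
  hemi_change <- c(FALSE, layout$hemisphere[-1L] != layout$hemisphere[-nrow(layout)])
  grp_change <- c(TRUE, grp[-1L] != grp[-nrow(layout)]) | hemi_change
  attr(layout, "group_boundaries") <- which(grp_change)
  attr(layout, "hemisphere_split") <- nrow(left)
  class(layout) <- c("column_layout", class(layout))
  layout
}

#' @export
print.column_layout <- function(x, ...) {
  cat("<column_layout> ", nrow(x), " columns (",
      attr(x, "hemisphere_split"), " L | ",
      nrow(x) - attr(x, "hemisphere_split"), " R), ",
      length(attr(x, "group_boundaries")), " group blocks\n", sep = "")
  NextMethod()
}
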