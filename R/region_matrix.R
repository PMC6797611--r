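#' Region-by-subject matrices
#'
#' The central data structure: an M x N numeric matrix `S` whose entry
#' `S[i, j]` summarizes subject `j`'s map over atlas area `i` (mean by
#' default). Regions that have no voxels in a subject's warped atlas
#' are `NA` — explicitly missing, never silently zero. The object is a
#' plain matrix with `region_labels` / `region_names` / `subject_ids`
#' / `statistic` attributes; [tidy()] gives the long tibble form.
#'
#' @name region_matrix
NULL

new_region_matrix <- function(S, region_labels, region_names, subject_ids,
                              statistic, sizes = NULL) {
  S <- as.matrix(S)
  dimnames(S) <- NULL
  stopifnot(nrow(S) == length(region_labels), ncol(S) == length(subject_ids))
  structure(S,
            region_labels = as.integer(region_labels),
            region_names = as.character(region_names),
            subject_ids = as.character(subject_ids),
            statistic = statistic,
            sizes = sizes,
            class = c("region_matrix", "matrix", "array"))
}

#' @export
print.region_matrix <- function(x, ...) {
  cat("<region_matrix> ", nrow(x), " regions x ", ncol(x), " subjects, statistic '",
      attr(x, "statistic"), "', ", sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Long-format view of a region matrix
#'
#' @param x A `region_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `label`, `name_area`, `subject_id`, `value`.
#' @method tidy region_matrix
#' @export
tidy.region_matrix <- function(x, ...) {
  tibble::tibble(
    label = rep(attr(x, "region_labels"), times = ncol(x)),
    name_area = rep(attr(x, "region_names"), times = ncol(x)),
    subject_id = rep(attr(x, "subject_ids"), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' One-row summary of a region matrix
#'
#' @param x A `region_matrix`.
#' @param ... Unused.
#' @method glance region_matrix
#' @export
glance.region_matrix <- function(x, ...) {
  v <- as.vector(x)
  tibble::tibble(
    n_regions = nrow(x), n_subjects = ncol(x),
    statistic = attr(x, "statistic"),
    n_missing = sum(is.na(v)),
    min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE)
  )
}

region_stat_fun <- function(statistic) {
  switch(statistic,
         mean = function(v) mean(v),
         min = function(v) min(v),
         max = function(v) max(v),
         sd = function(v) stats::sd(v),
         median = function(v) stats::median(v),
         stop("Unknown statistic '", statistic,
              "'; use one of mean, min, max, sd, median.", call. = FALSE))
}

#' Summarize one subject's map over every atlas area
#'
#' For each area `i` of the definition, applies `statistic` to the map
#' voxels where the subject's label volume equals the area's label.
#' Areas with zero voxels yield `NA`. Non-finite map voxels inside an
#' area are excluded from the statistic, with a warning giving their
#' count (background voxels may be non-finite without complaint).
#'
#' @param map A [scalar_volume()].
#' @param atlas A [label_volume()] on the same grid.
#' @param definition An [atlas_definition()].
#' @param statistic One of `"mean"` (default), `"min"`, `"max"`,
#'   `"sd"`, `"median"`.
#' @return Tibble with columns `label`, `name_area`, `value`,
#'   `n_voxels` in definition order.
#' @export
extract_region_values <- function(map, atlas, definition, statistic = "mean") {
  stopifnot(inherits(map, "scalar_volume"), inherits(atlas, "label_volume"),
            inherits(definition, "atlas_definition"))
  if (!identical(dim(map$grid), dim(atlas$grid))) {
    stop("Map grid ", paste(dim(map$grid), collapse = "x"),
         " does not match atlas grid ", paste(dim(atlas$grid), collapse = "x"), ".",
         call. = FALSE)
  }
  fun <- region_stat_fun(statistic)
  lab <- as.vector(atlas$grid)
  val <- as.vector(map$grid)
  inside <- lab > 0L
  n_bad <- sum(!is.finite(val[inside]))
  if (n_bad > 0L) {
    warning(n_bad, " non-finite voxel(s) inside labelled regions excluded ",
            "from the statistic.", call. = FALSE)
    keep <- !inside | is.finite(val)
    lab <- lab[keep]
    val <- val[keep]
    inside <- lab > 0L
  }
  groups <- split(val[inside], lab[inside])
  out <- tibble::tibble(
    label = definition$label,
    name_area = definition$name_area,
    value = NA_real_,
    n_voxels = 0L
  )
  hit <- match(as.character(out$label), names(groups))
  has <- !is.na(hit)
  out$value[has] <- vapply(groups[hit[has]], fun, numeric(1))
  out$n_voxels[has] <- lengths(groups[hit[has]])
  out
}

#' Declare a subject's input files
#'
#' @param subject_id Subject identifier shown in figures.
#' @param map_path Path to the subject's 3D scalar map (NIfTI).
#' @param atlas_path Path to the subject's coregistered label volume
#'   (NIfTI), same grid as the map.
#' @return A one-row tibble of class `subject_record`.
#' @export
subject_record <- function(subject_id, map_path, atlas_path) {
  for (p in c(map_path, atlas_path)) {
    if (!file.exists(p)) stop("File not found: ", p, call. = FALSE)
  }
  rec <- tibble::tibble(subject_id = as.character(subject_id),
                        map_path = map_path, atlas_path = atlas_path)
  class(rec) <- c("subject_record", class(rec))
  rec
}

#' Assemble the region-by-subject matrix S
#'
#' Iterates over subjects, summarizing each subject's map over every
#' atlas area; column `j` of the result is subject `j`'s region
#' vector. `records` may be a list of [subject_record()]s, a tibble
#' with columns `subject_id`/`map_path`/`atlas_path`, or a list of
#' `list(subject_id=, map=, atlas=)` entries carrying in-memory
#' volumes.
#'
#' @param records Subject inputs (see above); order fixes column order.
#' @param definition An [atlas_definition()].
#' @param statistic Summary statistic, see [extract_region_values()].
#' @return A [region_matrix] of size M x N.
#' @export
build_region_matrix <- function(records, definition, statistic = "mean") {
  stopifnot(inherits(definition, "atlas_definition"))
  if (is.data.frame(records)) {
    records <- purrr::pmap(records[c("subject_id", "map_path", "atlas_path")], list)
  }
  if (length(records) < 1L) stop("Need at least one subject record.", call. = FALSE)
  cols <- purrr::map(records, function(rec) {
    sid <- rec[["subject_id"]]
    res <- tryCatch({
      map <- if (!is.null(rec[["map"]])) rec[["map"]] else
        read_scalar_volume(rec[["map_path"]], sid)
      atl <- if (!is.null(rec[["atlas"]])) rec[["atlas"]] else
        read_label_volume(rec[["atlas_path"]], sid)
      extract_region_values(map, atl, definition, statistic)
    }, error = function(e) {
      stop("Extraction failed for subject '", sid, "': ", conditionMessage(e),
           call. = FALSE)
    })
    stats::setNames(res$value, res$label)
  })
  S <- do.call(cbind, cols)
  new_region_matrix(S, definition$label, definition$name_area,
                    purrr::map_chr(records, "subject_id"), statistic)
}

#' Average region matrices across sessions
#'
#' Element-wise mean over sessions of the same subjects, ignoring
#' missing entries; an entry stays missing only if it is missing in
#' every session.
#'
#' @param matrices List of [region_matrix] objects sharing region and
#'   subject order.
#' @return A [region_matrix].
#' @export
average_sessions <- function(matrices) {
  stopifnot(length(matrices) >= 1L, all(purrr::map_lgl(matrices, inherits, "region_matrix")))
  ref <- matrices[[1L]]
  for (m in matrices[-1L]) {
    if (!identical(attr(m, "region_labels"), attr(ref, "region_labels")) ||
        !identical(attr(m, "subject_ids"), attr(ref, "subject_ids"))) {
      stop("All sessions must share identical region and subject orderings.",
           call. = FALSE)
    }
  }
  arrs <- purrr::map(matrices, unclass)
  tot <- Reduce(`+`, purrr::map(arrs, function(a) ifelse(is.na(a), 0, a)))
  n <- Reduce(`+`, purrr::map(arrs, function(a) !is.na(a)))
  avg <- ifelse(n > 0L, tot / n, NA_real_)
  new_region_matrix(avg, attr(ref, "region_labels"), attr(ref, "region_names"),
                    attr(ref, "subject_ids"), attr(ref, "statistic"))
}

#' Write a region matrix as TSV
#'
#' Layout: one row per region; first two columns `label` and
#' `name_area`, then one column per subject (header row of subject
#' ids). Values are written with 12 significant digits so
#' [read_region_matrix()] round-trips them.
#'
#' @param S A [region_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_matrix <- function(S, path) {
  stopifnot(inherits(S, "region_matrix"))
  vals <- apply(unclass(S), 2L, function(col) {
    ifelse(is.na(col), "NA", formatC(col, digits = 12L, format = "g"))
  })
  vals <- matrix(vals, nrow = nrow(S))
  df <- data.frame(label = attr(S, "region_labels"),
                   name_area = attr(S, "region_names"), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("label", "name_area", attr(S, "subject_ids"))
  con <- file(path, "wb")  # binary connection: LF endings on every platform
  on.exit(close(con))
  writeLines(paste0("# statistic=", attr(S, "statistic")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region matrix from TSV
#'
#' @param path Path written by [write_region_matrix()].
#' @return A [region_matrix].
#' @export
read_region_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  statistic <- if (startsWith(first, "# statistic=")) {
    sub("^# statistic=", "", first)
  } else "mean"
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(df[, -(1:2), drop = FALSE])
  new_region_matrix(S, df$label, df$name_area, colnames(df)[-(1:2)], statistic)
}
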