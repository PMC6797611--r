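#' Assemble a run configuration
#'
#' Collects everything one fingerprint or comparison run needs. A
#' config round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]), and every run writes
#' a provenance log recording the resolved configuration, package
#' version and seed, so the run can be reproduced from its own
#' output directory.
#'
#' @param atlas_description Path to the atlas description TSV.
#' @param subjects Data frame with columns `subject_id`, `map_path`,
#'   `atlas_path`.
#' @param statistic Region summary statistic.
#' @param cluster Logical: cluster the subjects for display?
#' @param ap An [ap_parameters()] list.
#' @param binarize Optional binarization threshold for clustering.
#' @param template_sets Named list (one entry per smoothing level,
#'   e.g. `"0"`, `"3"`, `"6"`, `"9"`) of data frames shaped like
#'   `subjects`, holding the template-space maps for [run_compare()].
#' @param style A [brainglance_style()].
#' @param output_dir Where artifacts are written.
#' @param seed Integer seed recorded in the log.
#' @param column_map,header Passed to [read_atlas_description()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(atlas_description, subjects, statistic = "mean",
                       cluster = FALSE, ap = ap_parameters(), binarize = NULL,
                       template_sets = NULL, style = brainglance_style(),
                       output_dir = ".", seed = 1L,
                       column_map = c(label = 1L, name_area = 2L,
                                      name_largescale_region = 3L,
                                      hemisphere = 4L),
                       header = FALSE) {
  subjects <- tibble::as_tibble(subjects)
  subjects <- tibble::tibble(subject_id = subjects$subject_id,
                             map_path = subjects$map_path,
                             atlas_path = subjects$atlas_path)
  structure(list(atlas_description = atlas_description,
                 subjects = subjects,
                 statistic = statistic, cluster = cluster, ap = ap,
                 binarize = binarize, template_sets = template_sets,
                 style = style, output_dir = output_dir,
                 seed = as.integer(seed),
                 column_map = column_map, header = header),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every referenced path before any computation starts.
#'
#' @param config A [run_config()].
#' @return `config`, invisibly; errors on the first problem.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$atlas_description)) {
    stop("Atlas description not found: ", config$atlas_description, call. = FALSE)
  }
  check_set <- function(df, what) {
    needed <- c("subject_id", "map_path", "atlas_path")
    if (!all(needed %in% names(df))) {
      stop(what, " needs columns ", paste(needed, collapse = ", "), call. = FALSE)
    }
    for (p in c(df$map_path, df$atlas_path)) {
      if (!file.exists(p)) stop(what, ": file not found: ", p, call. = FALSE)
    }
  }
  check_set(config$subjects, "subjects")
  for (nm in names(config$template_sets)) {
    tpl <- tibble::as_tibble(config$template_sets[[nm]])
    check_set(tpl, paste0("template set '", nm, "'"))
    if (!identical(tpl$subject_id, config$subjects$subject_id)) {
      stop("Template set '", nm, "' lists different subjects than the ",
           "native set.", call. = FALSE)
    }
  }
  invisible(config)
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `path` invisibly ([write_run_config()]); a [run_config()]
#'   ([read_run_config()]).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- list(
    atlas_description = config$atlas_description,
    subjects = config$subjects,
    statistic = config$statistic,
    cluster = config$cluster,
    ap = unclass(config$ap),
    binarize = config$binarize,
    template_sets = purrr::map(config$template_sets, tibble::as_tibble),
    style = unclass(config$style),
    output_dir = config$output_dir,
    seed = config$seed,
    column_map = as.list(config$column_map),
    header = config$header
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(readLines(path), simplifyDataFrame = TRUE)
  run_config(
    atlas_description = raw$atlas_description,
    subjects = tibble::as_tibble(raw$subjects),
    statistic = raw$statistic,
    cluster = isTRUE(raw$cluster),
    ap = do.call(ap_parameters, raw$ap),
    binarize = raw$binarize,
    template_sets = if (length(raw$template_sets))
      purrr::map(raw$template_sets, tibble::as_tibble) else NULL,
    style = do.call(brainglance_style, raw$style),
    output_dir = raw$output_dir,
    seed = raw$seed,
    column_map = unlist(raw$column_map),
    header = isTRUE(raw$header)
  )
}

write_run_log <- function(config, path, stage, extra = list()) {
  payload <- c(list(stage = stage,
                    package_version = as.character(utils::packageVersion("brainglance")),
                    r_version = as.character(getRversion()),
                    seed = config$seed,
                    statistic = config$statistic,
                    cluster = config$cluster,
                    ap = unclass(config$ap),
                    binarize = config$binarize,
                    atlas_description = config$atlas_description,
                    n_subjects = nrow(config$subjects)),
               extra)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Run the fingerprint pipeline
#'
#' parse atlas description -> extract region values per subject ->
#' optional subject clustering -> render. Writes into
#' `config$output_dir`: `region_matrix.tsv`, `fingerprint.svg`,
#' optionally `clusters.json` + `cluster_matrix.tsv`, and
#' `fingerprint_log.json` with versions, parameters and seed.
#'
#' @param config A [run_config()].
#' @return Invisible list with `matrix`, `layout`, `clusters` (or
#'   `NULL`) and the output paths.
#' @export
run_fingerprint <- function(config) {
  validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  definition <- read_atlas_description(config$atlas_description,
                                       column_map = config$column_map,
                                       header = config$header)
  layout <- build_column_layout(definition)
  S <- build_region_matrix(config$subjects, definition, config$statistic)
  paths <- list(matrix = file.path(config$output_dir, "region_matrix.tsv"),
                figure = file.path(config$output_dir, "fingerprint.svg"),
                log = file.path(config$output_dir, "fingerprint_log.json"))
  write_region_matrix(S, paths$matrix)
  clusters <- NULL
  shown <- S
  if (isTRUE(config$cluster)) {
    clusters <- cluster_subjects(S, config$ap, binarize = config$binarize)
    shown <- summarize_clusters(S, clusters)
    paths$clusters <- file.path(config$output_dir, "clusters.json")
    paths$cluster_matrix <- file.path(config$output_dir, "cluster_matrix.tsv")
    clusters_to_json(clusters, paths$clusters)
    write_region_matrix(shown, paths$cluster_matrix)
  }
  render_brainglance(shown, layout, config$style, paths$figure)
  write_run_log(config, paths$log, "fingerprint",
                list(n_regions = nrow(S),
                     n_clusters = if (is.null(clusters)) NULL
                     else length(clusters$sizes),
                     outputs = unlist(paths)))
  invisible(list(matrix = S, layout = layout, clusters = clusters,
                 paths = paths))
}

#' Run the native-vs-template comparison pipeline
#'
#' For every template-space map set in `config$template_sets` (one per
#' smoothing level), builds both region matrices, takes the
#' native-minus-template differences, runs the per-region one-sample
#' t-test, and writes `comparison_<level>.tsv` plus the two-panel
#' figure `comparison_<level>.svg`, and a log.
#'
#' @param config A [run_config()] with non-empty `template_sets`.
#' @param alpha Significance level for the thresholded panel.
#' @return Invisible named list (per level) of lists with
#'   `comparison`, `differences` and paths.
#' @export
run_compare <- function(config, alpha = 0.05) {
  validate_run_config(config)
  if (!length(config$template_sets)) {
    stop("`config$template_sets` is empty; nothing to compare.", call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  definition <- read_atlas_description(config$atlas_description,
                                       column_map = config$column_map,
                                       header = config$header)
  layout <- build_column_layout(definition)
  S_native <- build_region_matrix(config$subjects, definition, config$statistic)
  results <- purrr::imap(config$template_sets, function(tpl, level) {
    S_tpl <- build_region_matrix(tibble::as_tibble(tpl), definition,
                                 config$statistic)
    D <- region_differences(S_native, S_tpl)
    cmp <- ttest_per_region(D, alpha = alpha)
    tsv <- file.path(config$output_dir, paste0("comparison_", level, ".tsv"))
    fig <- file.path(config$output_dir, paste0("comparison_", level, ".svg"))
    write_comparison(cmp, tsv)
    render_comparison(cmp, layout, config$style, fig)
    list(comparison = cmp, differences = D, paths = list(tsv = tsv, figure = fig))
  })
  write_run_log(config, file.path(config$output_dir, "compare_log.json"),
                "compare", list(levels = names(config$template_sets),
                                alpha = alpha))
  invisible(results)
}
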