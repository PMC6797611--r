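#' Phantom atlas specification
#'
#' @param grid_shape Integer length-3 volume shape.
#' @param n_gross_regions Number of gross anatomical groups.
#' @param areas_per_region Areas per gross region per hemisphere.
#' @param voxel_size Voxel edge, mm.
#' @param seed RNG seed (mandatory: generators are pure functions of
#'   their spec).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(16L, 16L, 16L), n_gross_regions = 2L,
                         areas_per_region = 2L, voxel_size = c(3, 3, 3),
                         seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  spec <- list(grid_shape = as.integer(grid_shape),
               n_gross_regions = as.integer(n_gross_regions),
               areas_per_region = as.integer(areas_per_region),
               voxel_size = as.numeric(voxel_size), seed = as.integer(seed))
  M <- 2L * spec$n_gross_regions * spec$areas_per_region
  interior <- pmax(spec$grid_shape - 2L, 0L)  # one voxel of background margin
  if (prod(interior) < 8L * M) {
    stop(M, " areas at >= 8 voxels each do not fit in a ",
         paste(spec$grid_shape, collapse = "x"), " grid.", call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

#' Generate a mirrored phantom atlas
#'
#' Builds a label volume plus matching definition: the left half of
#' the x axis carries the L areas, the right half their mirrored R
#' partners, with gross regions stacked along z and areas along y.
#' Each area is a contiguous block of at least 8 voxels; a margin of
#' background (label 0) surrounds everything. Deterministic given the
#' spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `atlas` ([label_volume()]) and
#'   `definition` ([atlas_definition()]).
#' @export
make_phantom_atlas <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  grid <- array(0L, dim = g)
  n_g <- spec$n_gross_regions
  n_a <- spec$areas_per_region
  # carve blocks inside a one-voxel background margin: x split at the
  # midline for hemispheres, z by gross region, y by area
  int_x <- 2:(g[1] - 1L)
  halfn <- floor(length(int_x) / 2)
  z_edges <- round(seq(2, g[3], length.out = n_g + 1))
  y_edges <- round(seq(2, g[2], length.out = n_a + 1))
  rows <- list()
  lab <- 0L
  for (hemi in c("L", "R")) {
    xs <- if (hemi == "L") int_x[seq_len(halfn)] else
      int_x[(length(int_x) - halfn + 1L):length(int_x)]
    for (gi in seq_len(n_g)) {
      for (ai in seq_len(n_a)) {
        lab <- lab + 1L
        zs <- z_edges[gi]:(z_edges[gi + 1] - 1L)
        ys <- y_edges[ai]:(y_edges[ai + 1] - 1L)
        if (length(xs) * length(ys) * length(zs) < 8L) {
          stop("Area block too small; enlarge the grid.", call. = FALSE)
        }
        grid[xs, ys, zs] <- lab
        rows[[lab]] <- tibble::tibble(
          label = lab,
          name_area = sprintf("G%d_%d_%d", gi, n_a, ai),
          name_largescale_region = sprintf("G%d", gi),
          hemisphere = hemi)
      }
    }
  }
  definition <- atlas_definition(dplyr::bind_rows(rows))
  list(atlas = label_volume(grid, voxel_size = spec$voxel_size,
                            space_tag = sprintf("phantom-seed%d", spec$seed)),
       definition = definition)
}

#' Group-effect specification for subject maps
#'
#' @param n_subjects Number of subjects.
#' @param n_clusters Number of planted subgroups (`<= n_subjects`).
#' @param cluster_region_means Numeric `n_clusters x M` matrix of
#'   planted per-region means, or `NULL` to draw them from
#'   `N(0, between_sd^2)`.
#' @param between_sd SD of drawn cluster means when
#'   `cluster_region_means` is `NULL`.
#' @param noise_sd Within-subject i.i.d. voxel noise SD (> 0).
#' @param seed RNG seed.
#' @return A list of class `group_effect_spec`.
#' @export
group_effect_spec <- function(n_subjects, n_clusters = 1L,
                              cluster_region_means = NULL, between_sd = 1,
                              noise_sd = 0.1, seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (n_clusters > n_subjects) {
    stop("`n_clusters` cannot exceed `n_subjects`.", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be positive.", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_clusters = as.integer(n_clusters),
                 cluster_region_means = cluster_region_means,
                 between_sd = between_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "group_effect_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Generate subject maps with planted subgroup structure
#'
#' Subject `j` in planted cluster `c` gets, in every voxel of region
#' `i`, the planted mean `cluster_region_means[c, i]` plus i.i.d.
#' Gaussian noise; background voxels carry noise only. Subjects are
#' dealt to clusters round-robin so all clusters are populated.
#'
#' @param atlas [label_volume()] from [make_phantom_atlas()].
#' @param definition Matching [atlas_definition()].
#' @param effects A [group_effect_spec()].
#' @return List with `maps` (list of [scalar_volume()]),
#'   `cluster_of` (planted cluster per subject) and `means`
#'   (the planted cluster-by-region matrix).
#' @export
make_subject_maps <- function(atlas, definition, effects) {
  stopifnot(inherits(atlas, "label_volume"),
            inherits(definition, "atlas_definition"),
            inherits(effects, "group_effect_spec"))
  M <- nrow(definition)
  with_seed(effects$seed, {
    means <- effects$cluster_region_means
    if (is.null(means)) {
      means <- matrix(stats::rnorm(effects$n_clusters * M, sd = effects$between_sd),
                      nrow = effects$n_clusters)
    }
    if (!identical(dim(means), c(effects$n_clusters, M))) {
      stop("`cluster_region_means` must be ", effects$n_clusters, " x ", M, ".",
           call. = FALSE)
    }
    cluster_of <- rep_len(seq_len(effects$n_clusters), effects$n_subjects)
    region_idx <- match(atlas$grid, definition$label)   # NA for background
    maps <- purrr::map(seq_len(effects$n_subjects), function(j) {
      base <- means[cluster_of[j], region_idx]
      base[is.na(base)] <- 0
      vox <- base + stats::rnorm(length(base), sd = effects$noise_sd)
      scalar_volume(array(vox, dim = dim(atlas$grid)),
                    voxel_size = atlas$voxel_size,
                    space_tag = sprintf("sub-%02d", j))
    })
    list(maps = maps, cluster_of = cluster_of, means = means)
  })
}

#' Generate a 4D time series with planted connectivity hubs
#'
#' Every voxel gets i.i.d. Gaussian noise over time; the designated
#' hub voxels share one latent signal that is also mixed, at
#' `hub_strength`, into the series of every other masked voxel, so a
#' hub correlates with the whole volume and should dominate an
#' eigenvector-centrality map.
#'
#' @param grid_shape Integer length-3 spatial shape.
#' @param T Number of volumes (>= 10).
#' @param hub_voxels Integer matrix (rows = voxels, columns x/y/z) or
#'   `NULL` for no hub.
#' @param hub_strength Mixing weight of the latent signal, >= 0.
#' @param tr_seconds Repetition time, seconds.
#' @param seed RNG seed.
#' @param voxel_size Voxel edge, mm.
#' @return A [ts_volume()].
#' @export
make_synthetic_timeseries <- function(grid_shape, T, hub_voxels = NULL,
                                      hub_strength = 0, tr_seconds = 2.2,
                                      seed, voxel_size = c(3, 3, 3)) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (T < 10L) stop("`T` must be at least 10.", call. = FALSE)
  g <- as.integer(grid_shape)
  with_seed(seed, {
    nvox <- prod(g)
    X <- matrix(stats::rnorm(nvox * T), nrow = nvox)
    if (!is.null(hub_voxels) && hub_strength > 0) {
      hub_voxels <- matrix(as.integer(hub_voxels), ncol = 3L)
      latent <- stats::rnorm(T)
      hub_lin <- hub_voxels[, 1] + (hub_voxels[, 2] - 1L) * g[1] +
        (hub_voxels[, 3] - 1L) * g[1] * g[2]
      # hubs are dominated by the latent signal; everyone else receives
      # a weaker echo of it
      X[hub_lin, ] <- matrix(rep(latent, each = length(hub_lin)),
                             nrow = length(hub_lin)) + 0.3 * X[hub_lin, ]
      others <- setdiff(seq_len(nvox), hub_lin)
      X[others, ] <- X[others, ] +
        hub_strength * matrix(rep(latent, each = length(others)),
                              nrow = length(others))
    }
    ts_volume(array(X, dim = c(g, T)), tr_seconds = tr_seconds,
              voxel_size = voxel_size)
  })
}

#' Write a complete demo dataset to a directory
#'
#' Generates a phantom atlas, planted-subgroup subject maps and a
#' matching "template-space" variant of each map (optionally
#' smoothed), writes everything as NIfTI plus the atlas description
#' TSV, and returns the file manifest. This is the dataset the
#' command-line `simulate` subcommand produces.
#'
#' @param dir Output directory (created if needed).
#' @param n_subjects Number of subjects.
#' @param n_gross_regions,areas_per_region,grid_shape Phantom layout,
#'   see [phantom_spec()].
#' @param n_clusters Planted subgroups.
#' @param noise_sd Voxel noise SD.
#' @param seed RNG seed.
#' @return Tibble of class `subject_record` rows (`subject_id`,
#'   `map_path`, `atlas_path`) with the atlas description path and
#'   planted labels as attributes.
#' @export
write_demo_dataset <- function(dir, n_subjects = 10L, n_gross_regions = 4L,
                               areas_per_region = 4L,
                               grid_shape = c(24L, 24L, 24L),
                               n_clusters = 2L, noise_sd = 0.1, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- phantom_spec(grid_shape = grid_shape,
                       n_gross_regions = n_gross_regions,
                       areas_per_region = areas_per_region, seed = seed)
  ph <- make_phantom_atlas(spec)
  eff <- group_effect_spec(n_subjects = n_subjects, n_clusters = n_clusters,
                           noise_sd = noise_sd, seed = seed + 1L)
  sm <- make_subject_maps(ph$atlas, ph$definition, eff)
  descr_path <- file.path(dir, "atlas_description.tsv")
  write_atlas_description(ph$definition, descr_path)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  write_volume(ph$atlas, atlas_path)
  recs <- purrr::map(seq_len(n_subjects), function(j) {
    mp <- file.path(dir, sprintf("sub-%02d_map.nii.gz", j))
    write_volume(sm$maps[[j]], mp)
    tibble::tibble(subject_id = sprintf("sub-%02d", j),
                   map_path = mp, atlas_path = atlas_path)
  })
  out <- dplyr::bind_rows(recs)
  attr(out, "atlas_description") <- descr_path
  attr(out, "cluster_of") <- sm$cluster_of
  attr(out, "seed") <- seed
  class(out) <- c("subject_record", class(out))
  out
}
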