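#' Volume containers
#'
#' Light S3 containers around plain 3D/4D arrays. The package never
#' resamples: volumes that are used together (a subject map and its
#' warped atlas) must already live on the same grid, and the NIfTI
#' affine is carried through I/O untouched.
#'
#' @name volumes
NULL

#' Create a scalar volume
#'
#' A 3D grid of real values, e.g. an eigenvector-centrality, regional
#' homogeneity or GLM contrast map for one subject.
#'
#' @param grid 3D numeric array.
#' @param voxel_size Numeric length-3 vector, voxel edge lengths in mm.
#' @param space_tag Free-text identifier of the coordinate space
#'   (a subject id, `"MNI"`, ...).
#' @param affine Optional 4x4 affine carried through to NIfTI output.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(grid, voxel_size = c(1, 1, 1), space_tag = "unknown",
                          affine = NULL) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3L) {
    stop("`grid` must be a 3D array, got ", length(dim(grid)), " dimensions.",
         call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive numbers (mm).", call. = FALSE)
  }
  structure(
    list(grid = grid, voxel_size = voxel_size, space_tag = as.character(space_tag)[1],
         affine = affine),
    class = "scalar_volume"
  )
}

#' Create a label volume
#'
#' A 3D grid of non-negative integer atlas labels in a subject's space.
#' 0 is background. Label volumes must only ever be produced or
#' resampled with nearest-neighbour interpolation so the labels stay
#' integral; a grid with fractional values is rejected.
#'
#' @inheritParams scalar_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, voxel_size = c(1, 1, 1), space_tag = "unknown",
                         affine = NULL) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3L) {
    stop("`grid` must be a 3D array.", call. = FALSE)
  }
  if (any(!is.finite(grid)) || any(grid != round(grid)) || any(grid < 0)) {
    stop("Label volume must contain only non-negative integers ",
         "(nearest-neighbour resampling required).", call. = FALSE)
  }
  storage.mode(grid) <- "integer"
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive numbers (mm).", call. = FALSE)
  }
  structure(
    list(grid = grid, voxel_size = voxel_size, space_tag = as.character(space_tag)[1],
         affine = affine),
    class = "label_volume"
  )
}

#' Create a 4D time-series volume
#'
#' @param grid 4D numeric array (x, y, z, t).
#' @param tr_seconds Repetition time in seconds.
#' @param mask 3D logical array of in-brain voxels; defaults to all
#'   voxels whose series is finite and non-constant in variance terms.
#' @param voxel_size Numeric length-3, mm.
#' @return An object of class `ts_volume`.
#' @export
ts_volume <- function(grid, tr_seconds, mask = NULL, voxel_size = c(1, 1, 1)) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 4L) {
    stop("`grid` must be a 4D array (x, y, z, t).", call. = FALSE)
  }
  if (dim(grid)[4] < 2L) {
    stop("Time series needs at least 2 volumes.", call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("`tr_seconds` must be a single positive number.", call. = FALSE)
  }
  sp <- dim(grid)[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, dim = sp)
  }
  mask <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (!identical(dim(mask), sp)) {
    stop("`mask` shape ", paste(dim(mask), collapse = "x"),
         " does not match spatial shape ", paste(sp, collapse = "x"), ".",
         call. = FALSE)
  }
  flat <- matrix(grid, nrow = prod(sp))
  bad <- which(mask) [!apply(flat[which(mask), , drop = FALSE], 1L,
                             function(x) all(is.finite(x)))]
  if (length(bad)) {
    stop("Masked-in voxels with non-finite series at linear indices: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  }
  structure(
    list(grid = grid, tr_seconds = tr_seconds, mask = mask,
         voxel_size = as.numeric(voxel_size)),
    class = "ts_volume"
  )
}

#' Read a scalar map from NIfTI
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param space_tag Optional space identifier stored on the volume.
#' @return A [scalar_volume()].
#' @export
read_scalar_volume <- function(path, space_tag = basename(path)) {
  img <- RNifti::readNifti(path)
  scalar_volume(unclass(as.array(img)),
                voxel_size = abs(RNifti::pixdim(img)[1:3]),
                space_tag = space_tag,
                affine = RNifti::xform(img))
}

#' Read a label volume from NIfTI
#'
#' @inheritParams read_scalar_volume
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, space_tag = basename(path)) {
  img <- RNifti::readNifti(path)
  label_volume(unclass(as.array(img)),
               voxel_size = abs(RNifti::pixdim(img)[1:3]),
               space_tag = space_tag,
               affine = RNifti::xform(img))
}

#' Write a volume to NIfTI
#'
#' @param vol A [scalar_volume()], [label_volume()] or [ts_volume()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("scalar_volume", "label_volume", "ts_volume")))
  pd <- if (inherits(vol, "ts_volume")) c(vol$voxel_size, vol$tr_seconds) else vol$voxel_size
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$grid), collapse = "x"),
      " @ ", paste(signif(x$voxel_size, 3), collapse = "x"), " mm, space '",
      x$space_tag, "'\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$grid))), 0L)
  cat("<label_volume> ", paste(dim(x$grid), collapse = "x"), " @ ",
      paste(signif(x$voxel_size, 3), collapse = "x"), " mm, ",
      length(labs), " labels, space '", x$space_tag, "'\n", sep = "")
  invisible(x)
}

#' @export
print.ts_volume <- function(x, ...) {
  cat("<ts_volume> ", paste(dim(x$grid), collapse = "x"),
      ", TR ", x$tr_seconds, " s, ", sum(x$mask), " masked voxels\n", sep = "")
  invisible(x)
}
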