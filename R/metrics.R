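#' Temporal high-pass filter via discrete-cosine projection
#'
#' Removes slow drifts from every voxel's series by projecting onto a
#' low-frequency discrete-cosine basis and returning the residual.
#' The basis spans the constant plus all cosines with period longer
#' than `cutoff_seconds`; its dimension is
#' `floor(2 * T * tr / cutoff) + 1` including the constant, so the
#' voxel mean is always removed. Deterministic and closed-form, which
#' makes the filter directly testable against an explicit basis
#' regression.
#'
#' @param ts A [ts_volume()].
#' @param cutoff_seconds High-pass cutoff period in seconds
#'   (e.g. 100 for the conventional 1/100 s cutoff frequency).
#' @return A [ts_volume()] of filtered series; voxels outside the
#'   mask are zeroed.
#' @export
highpass_filter <- function(ts, cutoff_seconds) {
  stopifnot(inherits(ts, "ts_volume"))
  T <- dim(ts$grid)[4]
  tr <- ts$tr_seconds
  if (!is.numeric(cutoff_seconds) || cutoff_seconds <= 2 * tr) {
    stop("`cutoff_seconds` must exceed twice the TR (", 2 * tr, " s).",
         call. = FALSE)
  }
  K <- floor(2 * T * tr / cutoff_seconds) + 1L
  if (K >= T) {
    stop("Cutoff ", cutoff_seconds, " s needs a ", K,
         "-dimensional drift basis but the series has only ", T, " volumes.",
         call. = FALSE)
  }
  B <- dct_basis(T, K)
  sp <- dim(ts$grid)[1:3]
  X <- matrix(ts$grid, nrow = prod(sp))        # voxels x time
  idx <- which(ts$mask)
  Xm <- t(X[idx, , drop = FALSE])              # time x voxels
  resid <- Xm - B %*% crossprod(B, Xm)         # B is orthonormal
  out <- matrix(0, nrow = prod(sp), ncol = T)
  out[idx, ] <- t(resid)
  ts_volume(array(out, dim = dim(ts$grid)), tr_seconds = tr, mask = ts$mask,
            voxel_size = ts$voxel_size)
}

# orthonormal DCT-II basis, columns k = 0 .. K-1 over T points
dct_basis <- function(T, K) {
  t <- seq_len(T) - 1L
  B <- vapply(seq_len(K) - 1L, function(k) {
    col <- cos(pi * k * (2 * t + 1) / (2 * T))
    col / sqrt(sum(col^2))
  }, numeric(T))
  matrix(B, nrow = T)
}

#' Eigenvector centrality map
#'
#' Summarizes a 4D series as one 3D map of network centrality: the
#' dominant eigenvector of the voxel-by-voxel similarity matrix
#' `A[u, v] = (r[u, v] + 1) / 2`, where `r` is the Pearson correlation
#' of the two voxels' series. The +1 shift makes `A` non-negative, so
#' by Perron-Frobenius the dominant eigenvector is unique and can be
#' taken entry-wise non-negative; a hub voxel whose series co-varies
#' with many others gets a large entry. `A` is never materialized:
#' with row-standardized data `Z` (unit-norm centered series as
#' columns), `A %*% x = (Z %*% (t(Z) %*% x) + sum(x)) / 2`, giving an
#' O(n*T) power iteration. The returned map has unit Euclidean norm
#' over the mask and zeros outside it.
#'
#' @param ts A [ts_volume()] with at least 2 masked voxels, each with
#'   non-zero temporal variance.
#' @param tol Relative eigenvalue-change convergence tolerance.
#' @param max_iterations Iteration cap for the power method.
#' @param init Optional start vector (length = masked voxels); default
#'   is the uniform positive vector, which already lies in the
#'   Perron cone.
#' @return A [scalar_volume()] of centralities.
#' @export
compute_ecm <- function(ts, tol = 1e-12, max_iterations = 10000L, init = NULL) {
  stopifnot(inherits(ts, "ts_volume"))
  sp <- dim(ts$grid)[1:3]
  idx <- which(ts$mask)
  n <- length(idx)
  if (n < 2L) stop("ECM needs at least 2 masked voxels.", call. = FALSE)
  T <- dim(ts$grid)[4]
  X <- matrix(ts$grid, nrow = prod(sp))[idx, , drop = FALSE]  # voxels x time
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  zero_var <- which(nrm == 0)
  if (length(zero_var)) {
    stop("Masked voxel(s) with zero temporal variance at linear indices: ",
         paste(utils::head(idx[zero_var], 10L), collapse = ", "),
         if (length(zero_var) > 10L) ", ..." else "", call. = FALSE)
  }
  Z <- Xc / nrm                                 # voxels x time, unit-norm rows
  x <- if (is.null(init)) rep(1 / sqrt(n), n) else abs(init) / sqrt(sum(init^2))
  lambda <- 0
  for (it in seq_len(max_iterations)) {
    Ax <- (Z %*% crossprod(Z, x) + sum(x)) / 2  # r = Z Z^T; A = (r+1)/2
    Ax <- as.vector(Ax)
    lambda_new <- sqrt(sum(Ax^2))
    x <- Ax / lambda_new
    if (abs(lambda_new - lambda) <= tol * lambda_new) break
    lambda <- lambda_new
  }
  x <- abs(x)                                    # Perron vector is non-negative
  x <- x / sqrt(sum(x^2))
  out <- numeric(prod(sp))
  out[idx] <- x
  scalar_volume(array(out, dim = sp), voxel_size = ts$voxel_size,
                space_tag = "ecm")
}

# neighbourhood offset table: 7 = faces, 19 = faces+edges, 27 = full cube
neighborhood_offsets <- function(neighborhood) {
  if (!neighborhood %in% c(7L, 19L, 27L)) {
    stop("`neighborhood` must be 7, 19 or 27.", call. = FALSE)
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(neighborhood),
                 "7" = ord <= 1L, "19" = ord <= 2L, "27" = rep(TRUE, 27L))
  g[keep, , drop = FALSE]
}

#' Regional homogeneity map (Kendall's W)
#'
#' For every masked voxel, computes Kendall's coefficient of
#' concordance W over the time series of the voxel and its spatial
#' neighbours (faces only, faces+edges, or the full 3x3x3 cube).
#' Each series is ranked over time with mid-ranks for ties;
#' with `K` series of length `T`, rank sums `R_t` and tie correction
#' `C = sum over series of sum(g^3 - g)` over tie-group sizes `g`,
#' `W = 12 * sum((R_t - mean(R))^2) / (K^2 * (T^3 - T) - K * C)`.
#' W is 1 exactly when all neighbourhood series are rank-identical
#' and 0 under complete rank disagreement. Neighbourhoods are clipped
#' at the mask and volume borders, so the actual K varies there.
#'
#' @param ts A [ts_volume()] with T >= 3.
#' @param neighborhood 7, 19 or 27 (default) voxels.
#' @return A [scalar_volume()] with W in `[0, 1]` inside the mask and
#'   0 outside.
#' @export
compute_reho <- function(ts, neighborhood = 27L) {
  stopifnot(inherits(ts, "ts_volume"))
  T <- dim(ts$grid)[4]
  if (T < 3L) stop("ReHo needs at least 3 time points.", call. = FALSE)
  off <- neighborhood_offsets(as.integer(neighborhood))
  sp <- dim(ts$grid)[1:3]
  nvox <- prod(sp)
  X <- matrix(ts$grid, nrow = nvox)             # voxels x time
  # rank every masked series once; also record its tie correction
  idx <- which(ts$mask)
  ranks <- matrix(NA_real_, nrow = nvox, ncol = T)
  tie_corr <- numeric(nvox)
  ranks[idx, ] <- t(apply(X[idx, , drop = FALSE], 1L, rank))
  tie_corr[idx] <- apply(X[idx, , drop = FALSE], 1L, function(x) {
    g <- table(x)
    sum(g^3 - g)
  })
  coords <- arrayInd(idx, sp)
  W <- numeric(nvox)
  for (v in seq_along(idx)) {
    nb <- sweep(off, 2L, coords[v, ], `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= sp[1] &
      nb[, 2] >= 1L & nb[, 2] <= sp[2] &
      nb[, 3] >= 1L & nb[, 3] <= sp[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * sp[1] + (nb[ok, 3] - 1L) * sp[1] * sp[2]
    lin <- lin[ts$mask[lin]]
    W[idx[v]] <- kendall_w(ranks[lin, , drop = FALSE], tie_corr[lin], T)
  }
  scalar_volume(array(W, dim = sp), voxel_size = ts$voxel_size,
                space_tag = "reho")
}

# W from pre-ranked series (rows = series), with tie correction
kendall_w <- function(R, tie_corr, T) {
  K <- nrow(R)
  if (K < 1L) return(0)
  Rt <- colSums(R)
  S <- sum((Rt - mean(Rt))^2)
  denom <- K^2 * (T^3 - T) / 12 - K * sum(tie_corr) / 12
  if (denom <= 0) return(0)   # all series fully tied: no rank information
  S / denom
}

#' Gaussian smoothing of a 3D map
#'
#' Separable Gaussian convolution; the kernel width is given as full
#' width at half maximum in millimetres and converted per axis to
#' voxel units via `sigma = fwhm / sqrt(8 * log(2)) / voxel_size`.
#' Outside the volume the data is treated as zero (no mask
#' renormalization), so values within roughly `truncate * sigma` of
#' the border shrink towards zero; comparisons should use one fixed
#' rule throughout, and this is it. `fwhm_mm = 0` returns the input
#' unchanged.
#'
#' @param map A [scalar_volume()] with known positive voxel size.
#' @param fwhm_mm Kernel full width at half maximum, mm, >= 0.
#' @param truncate Kernel cutoff radius in standard deviations.
#' @return A [scalar_volume()].
#' @export
smooth_volume <- function(map, fwhm_mm, truncate = 4) {
  stopifnot(inherits(map, "scalar_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || is.na(fwhm_mm) || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a single non-negative number.", call. = FALSE)
  }
  if (fwhm_mm == 0) return(map)
  arr <- map$grid
  sigma_vox <- fwhm_mm / sqrt(8 * log(2)) / map$voxel_size
  for (axis in 1:3) {
    arr <- convolve_axis(arr, gauss_kernel(sigma_vox[axis], truncate), axis)
  }
  scalar_volume(arr, voxel_size = map$voxel_size, space_tag = map$space_tag,
                affine = map$affine)
}

gauss_kernel <- function(sigma, truncate) {
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# zero-padded 1D convolution along one axis of a 3D array, via a banded
# kernel matrix applied to the unfolded array
convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  Kmat <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    i <- seq_len(n)
    src <- i + j
    ok <- src >= 1L & src <= n
    Kmat[cbind(i[ok], src[ok])] <- Kmat[cbind(i[ok], src[ok])] + k[j + r + 1L]
  }
  sm <- Kmat %*% matrix(a, nrow = n)
  aperm(array(sm, dim = d[perm]), order(perm))
}
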