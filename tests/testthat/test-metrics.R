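flat_ts <- function(X, sp, tr = 2.2, mask = NULL) {
  # X: voxels x time -> ts_volume on spatial shape sp
  ts_volume(array(X, dim = c(sp, ncol(X))), tr_seconds = tr, mask = mask)
}

test_that("high-pass removes linear drift and constants, keeps white noise", {
  T <- 200L; tr <- 1
  drift <- seq(0, 10, length.out = T)
  set.seed(41)
  noise <- rnorm(T)
  X <- rbind(drift, noise, rep(5, T))
  ts <- flat_ts(X, c(3L, 1L, 1L), tr = tr)
  out <- highpass_filter(ts, cutoff_seconds = 100)
  filt <- matrix(out$grid, nrow = 3)

  expect_lt(max(abs(filt[1, ])), max(abs(drift)) / 10)
  centered <- noise - mean(noise)
  expect_gt(cor(filt[2, ], centered), 0.95)
  expect_equal(filt[3, ], rep(0, T))
  expect_lt(abs(mean(filt[2, ])), 1e-10)
})

test_that("high-pass equals explicit regression on the cosine drift basis", {
  T <- 120L; tr <- 2
  set.seed(42)
  x <- cumsum(rnorm(T))   # random walk, strong low-frequency content
  ts <- flat_ts(matrix(x, nrow = 1), c(1L, 1L, 1L), tr = tr)
  out <- highpass_filter(ts, cutoff_seconds = 90)
  got <- as.vector(out$grid)

  K <- floor(2 * T * tr / 90) + 1
  t0 <- 0:(T - 1)
  B <- sapply(0:(K - 1), function(k) cos(pi * k * (2 * t0 + 1) / (2 * T)))
  want <- as.vector(residuals(lm(x ~ B)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("high-pass rejects cutoffs the series cannot support", {
  ts <- flat_ts(matrix(rnorm(20), nrow = 1), c(1L, 1L, 1L), tr = 1)
  expect_error(highpass_filter(ts, cutoff_seconds = 1.5), "TR")
  # cutoff barely above 2*TR: drift basis dimension reaches T
  expect_error(highpass_filter(ts, cutoff_seconds = 2.05), "basis|volumes")
})

test_that("identical series force the uniform centrality vector", {
  T <- 30L
  set.seed(43)
  base <- rnorm(T)
  X <- matrix(rep(base, each = 8), nrow = 8)
  ecm <- compute_ecm(flat_ts(X, c(2L, 2L, 2L)))
  expect_equal(as.vector(ecm$grid), rep(1 / sqrt(8), 8), tolerance = 1e-8)
})

test_that("matrix-free centrality matches dense eigendecomposition", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- 50L; T <- 40L
    X <- matrix(rnorm(n * T), nrow = n)
    got <- compute_ecm(flat_ts(X, c(50L, 1L, 1L)))
    expect_lt(max(abs(as.vector(got$grid) - oracle_ecm_dense(X))), 1e-6)
  }
})

test_that("a planted hub attains the maximum centrality", {
  set.seed(44)
  T <- 150L; n <- 40L
  latent <- rnorm(T)
  X <- matrix(rnorm(n * T), nrow = n)
  X[-7, ] <- X[-7, ] + 1.2 * matrix(rep(latent, each = n - 1), nrow = n - 1)
  X[7, ] <- latent + 0.2 * X[7, ]   # hub: nearly the latent signal itself
  ecm <- compute_ecm(flat_ts(X, c(40L, 1L, 1L)))
  v <- as.vector(ecm$grid)
  expect_equal(which.max(v), 7L)
  expect_equal(which.max(oracle_ecm_dense(X)), 7L)
})

test_that("centrality is non-negative, unit norm, and correlation-invariant", {
  set.seed(45)
  n <- 30L; T <- 60L
  X <- matrix(rnorm(n * T), nrow = n)
  mask <- array(c(rep(TRUE, n), rep(FALSE, 6)), dim = c(6L, 6L, 1L))
  Xfull <- rbind(X, matrix(0, 6, T))
  v1 <- compute_ecm(flat_ts(Xfull, c(6L, 6L, 1L), mask = mask))
  vals <- as.vector(v1$grid)[as.vector(mask)]
  expect_true(all(vals >= 0))
  expect_equal(sum(vals^2), 1, tolerance = 1e-12)
  expect_true(all(as.vector(v1$grid)[!as.vector(mask)] == 0))

  a <- runif(n, 0.5, 3); b <- rnorm(n, sd = 10)
  Xfull2 <- rbind(a * X + b, matrix(0, 6, T))
  v2 <- compute_ecm(flat_ts(Xfull2, c(6L, 6L, 1L), mask = mask))
  expect_lt(max(abs(as.vector(v1$grid) - as.vector(v2$grid))), 1e-10)
})

test_that("zero-variance masked voxels are a hard error naming indices", {
  X <- rbind(rnorm(20), rep(3, 20))
  expect_error(compute_ecm(flat_ts(X, c(2L, 1L, 1L))), "zero temporal variance")
})

test_that("power iteration start vector does not change the result", {
  set.seed(46)
  X <- matrix(rnorm(25 * 50), nrow = 25)
  ts <- flat_ts(X, c(25L, 1L, 1L))
  v0 <- compute_ecm(ts)
  for (s in 1:3) {
    set.seed(s)
    vs <- compute_ecm(ts, init = runif(25))
    expect_lt(max(abs(as.vector(v0$grid) - as.vector(vs$grid))), 1e-8)
  }
})

test_that("perfectly concordant neighbourhoods give W = 1", {
  T <- 20L
  base <- seq_len(T) + 0.5
  X <- outer(rep(1, 27), base) * runif(27, 0.5, 2)  # monotone in t for all voxels
  reho <- compute_reho(flat_ts(X, c(3L, 3L, 3L)), neighborhood = 27L)
  expect_equal(as.vector(reho$grid), rep(1, 27), tolerance = 1e-12)
})

test_that("anti-concordant pair matches the closed-form rank computation", {
  T <- 10L
  s1 <- seq_len(T)          # ranks 1..T
  s2 <- rev(s1)             # reversed ranking
  X <- rbind(s1, s2)
  mask <- array(c(TRUE, TRUE), dim = c(2L, 1L, 1L))
  reho <- compute_reho(flat_ts(X, c(2L, 1L, 1L), mask = mask), neighborhood = 7L)
  want <- oracle_kendall_w(X)
  expect_equal(as.vector(reho$grid), rep(want, 2), tolerance = 1e-14)
  expect_equal(want, 0)     # complete disagreement of two rankings
})

test_that("regional homogeneity equals the independent rank oracle voxel-wise", {
  set.seed(47)
  sp <- c(10L, 10L, 10L); T <- 12L
  arr <- array(rnorm(prod(sp) * T), dim = c(sp, T))
  # ties exercised deliberately: round part of the volume to one decimal
  arr[1:5, , , ] <- round(arr[1:5, , , ], 1)
  mask <- array(runif(prod(sp)) > 0.1, dim = sp)
  ts <- ts_volume(arr, tr_seconds = 2.2, mask = mask)
  for (nb in c(7L, 27L)) {
    got <- compute_reho(ts, neighborhood = nb)$grid
    want <- oracle_reho(arr, mask, nb)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_true(all(got >= 0 & got <= 1 + 1e-12))
  }
})

test_that("degenerate homogeneity inputs are handled", {
  expect_error(compute_reho(flat_ts(matrix(rnorm(4), 2), c(2L, 1L, 1L))), "3 time")
  expect_error(compute_reho(
    flat_ts(matrix(rnorm(20), 2), c(2L, 1L, 1L)), neighborhood = 9L), "7, 19 or 27")
})

test_that("zero-width smoothing is the identity and constants are preserved", {
  set.seed(48)
  vol <- scalar_volume(array(rnorm(12^3), dim = c(12, 12, 12)), voxel_size = c(3, 3, 3))
  expect_identical(smooth_volume(vol, 0)$grid, vol$grid)
  const <- scalar_volume(array(7, dim = c(21, 21, 21)), voxel_size = c(3, 3, 3))
  sm <- smooth_volume(const, 6)
  expect_equal(sm$grid[11, 11, 11], 7, tolerance = 1e-9)
  expect_error(smooth_volume(vol, -1), "non-negative")
})

test_that("impulse response width matches the requested FWHM", {
  arr <- array(0, dim = c(31, 31, 31))
  arr[16, 16, 16] <- 1
  vol <- scalar_volume(arr, voxel_size = c(3, 3, 3))
  sm <- smooth_volume(vol, 6)$grid   # 6 mm FWHM on 3 mm voxels -> 2 voxels
  prof <- sm[, 16, 16]
  half <- max(prof) / 2
  # interpolated crossing points of the half maximum
  above <- which(prof >= half)
  x1 <- min(above); x2 <- max(above)
  f <- function(i, j) i + (half - prof[i]) / (prof[j] - prof[i]) * (j - i)
  width <- f(x2, x2 + 1) - f(x1, x1 - 1)
  expect_equal(width, 2, tolerance = 0.05)
})

test_that("smoothing kernels are separable and mass-preserving inside", {
  set.seed(49)
  vol <- scalar_volume(array(rnorm(10^3), dim = c(10, 10, 10)),
                       voxel_size = c(2, 2, 2))
  sm <- smooth_volume(vol, 4)
  # linearity: smoothing commutes with scaling and addition
  sm2 <- smooth_volume(scalar_volume(2 * vol$grid, voxel_size = c(2, 2, 2)), 4)
  expect_equal(sm2$grid, 2 * sm$grid, tolerance = 1e-12)
})
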