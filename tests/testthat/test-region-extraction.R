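make_two_region_fixture <- function() {
  atlas_arr <- array(0L, dim = c(4, 2, 1))
  atlas_arr[1:3, 1, 1] <- 1L
  atlas_arr[1, 2, 1] <- 2L
  map_arr <- array(0, dim = c(4, 2, 1))
  map_arr[1:3, 1, 1] <- c(1, 2, 3)
  map_arr[1, 2, 1] <- 10
  def <- suppressWarnings(atlas_definition(data.frame(
    label = 1:2, name_area = c("r1", "r2"),
    name_largescale_region = "G1", hemisphere = c("L", "R"))))
  list(map = scalar_volume(map_arr), atlas = label_volume(atlas_arr), def = def)
}

test_that("constant and hand-built maps give forced region values", {
  fx <- make_two_region_fixture()
  res <- extract_region_values(fx$map, fx$atlas, fx$def, "mean")
  expect_equal(res$value, c(2, 10))
  expect_equal(res$n_voxels, c(3L, 1L))

  one <- suppressWarnings(atlas_definition(data.frame(
    label = 1, name_area = "all", name_largescale_region = "G1",
    hemisphere = "L")))
  arr <- array(1L, dim = c(3, 3, 3))
  cmap <- scalar_volume(array(4.25, dim = c(3, 3, 3)))
  expect_equal(suppressWarnings(
    extract_region_values(cmap, label_volume(arr), one, "mean"))$value, 4.25)
})

test_that("every statistic equals an explicit per-voxel loop on random phantoms", {
  ph <- make_phantom_atlas(phantom_spec(grid_shape = c(16L, 16L, 16L),
                                        n_gross_regions = 2L,
                                        areas_per_region = 2L, seed = 3L))
  set.seed(99)
  map <- scalar_volume(array(rnorm(16^3), dim = c(16, 16, 16)))
  for (st in c("mean", "min", "max", "sd", "median")) {
    got <- extract_region_values(map, ph$atlas, ph$definition, st)$value
    want <- oracle_region_stat(map$grid, ph$atlas$grid, ph$definition$label, st)
    expect_equal(got, unname(want), tolerance = 0)
  }
})

test_that("shape mismatch and zero-voxel regions are handled as contracted", {
  fx <- make_two_region_fixture()
  small <- scalar_volume(array(0, dim = c(2, 2, 1)))
  expect_error(extract_region_values(small, fx$atlas, fx$def), "2x2x1.*4x2x1")

  def3 <- suppressWarnings(atlas_definition(data.frame(
    label = 1:3, name_area = c("r1", "r2", "ghost"),
    name_largescale_region = "G1", hemisphere = c("L", "R", "L"))))
  res <- suppressWarnings(extract_region_values(fx$map, fx$atlas, def3))
  expect_true(is.na(res$value[3]))
  expect_equal(res$n_voxels[3], 0L)
})

test_that("non-finite voxels inside regions are excluded with a warning", {
  fx <- make_two_region_fixture()
  fx$map$grid[2, 1, 1] <- NaN
  expect_warning(res <- extract_region_values(fx$map, fx$atlas, fx$def),
                 "non-finite")
  expect_equal(res$value[1], mean(c(1, 3)))
  # non-finite background voxels are silently fine
  fx2 <- make_two_region_fixture()
  fx2$map$grid[4, 2, 1] <- Inf
  expect_silent(extract_region_values(fx2$map, fx2$atlas, fx2$def))
})

test_that("mean extraction is permutation invariant and affine equivariant", {
  set.seed(7)
  arr <- array(sample(0:4, 10^3, replace = TRUE), dim = c(10, 10, 10))
  def <- suppressWarnings(atlas_definition(data.frame(
    label = 1:4, name_area = paste0("a", 1:4),
    name_largescale_region = "G1", hemisphere = c("L", "L", "R", "R"))))
  vals <- array(rnorm(10^3), dim = c(10, 10, 10))
  base <- extract_region_values(scalar_volume(vals), label_volume(arr), def)$value

  # voxel order permutation (consistent for map and atlas)
  p <- sample(1000)
  arr_p <- array(as.vector(arr)[p], dim = dim(arr))
  vals_p <- array(as.vector(vals)[p], dim = dim(vals))
  perm <- extract_region_values(scalar_volume(vals_p), label_volume(arr_p), def)$value
  expect_equal(perm, base)

  # affine map a*x + b
  aff <- extract_region_values(scalar_volume(2.5 * vals - 3), label_volume(arr), def)$value
  expect_equal(aff, 2.5 * base - 3)

  # order statistics bracket the median
  lo <- extract_region_values(scalar_volume(vals), label_volume(arr), def, "min")$value
  md <- extract_region_values(scalar_volume(vals), label_volume(arr), def, "median")$value
  hi <- extract_region_values(scalar_volume(vals), label_volume(arr), def, "max")$value
  expect_true(all(lo <= md & md <= hi))
})

test_that("region matrix stacks per-subject vectors in record order", {
  ph <- make_phantom_atlas(phantom_spec(grid_shape = c(12L, 12L, 12L),
                                        n_gross_regions = 2L,
                                        areas_per_region = 2L, seed = 5L))
  set.seed(12)
  recs <- lapply(1:10, function(j) {
    list(subject_id = sprintf("sub-%02d", j),
         map = scalar_volume(array(rnorm(12^3), dim = c(12, 12, 12))),
         atlas = ph$atlas)
  })
  S <- build_region_matrix(recs, ph$definition)
  expect_s3_class(S, "region_matrix")
  expect_equal(dim(S), c(8L, 10L))
  expect_equal(attr(S, "subject_ids"), sprintf("sub-%02d", 1:10))
  for (j in c(1, 4, 10)) {
    want <- extract_region_values(recs[[j]]$map, ph$atlas, ph$definition)$value
    expect_equal(unname(unclass(S)[, j]), want)
  }
  # duplicated subjects give identical columns
  S3 <- build_region_matrix(recs[c(1, 1, 1)], ph$definition)
  expect_equal(unclass(S3)[, 1], unclass(S3)[, 3])
})

test_that("a failing subject aborts with its id in the message", {
  ph <- make_phantom_atlas(phantom_spec(seed = 6L))
  bad <- list(subject_id = "sub-bad",
              map = scalar_volume(array(0, dim = c(2, 2, 2))),
              atlas = ph$atlas)
  expect_error(build_region_matrix(list(bad), ph$definition), "sub-bad")
})

test_that("session averaging is the masked element-wise mean", {
  X1 <- matrix(1, 4, 3); X2 <- matrix(3, 4, 3)
  s1 <- rm_from_matrix(X1); s2 <- rm_from_matrix(X2)
  avg <- average_sessions(list(s1, s2))
  expect_true(all(unclass(avg) == 2))
  expect_equal(unclass(average_sessions(list(s1))), unclass(s1))

  set.seed(21)
  sessions <- lapply(1:10, function(i) rm_from_matrix(matrix(rnorm(12), 4, 3)))
  got <- unclass(average_sessions(sessions))
  want <- Reduce(`+`, lapply(sessions, unclass)) / 10
  expect_equal(got, want)

  # missing in one session is ignored; missing everywhere stays missing
  Xna <- X1; Xna[1, 1] <- NA
  sna <- suppressWarnings(rm_from_matrix(Xna))
  avg2 <- average_sessions(list(sna, s2))
  expect_equal(unclass(avg2)[1, 1], 3)
  avg3 <- average_sessions(list(sna, sna))
  expect_true(is.na(unclass(avg3)[1, 1]))

  perm <- rm_from_matrix(X2[, c(2, 1, 3)])
  attr(perm, "subject_ids") <- c("s02", "s01", "s03")
  expect_error(average_sessions(list(s1, perm)), "ordering")
})

test_that("TSV serialization round-trips the matrix at full precision", {
  set.seed(31)
  X <- matrix(rnorm(20), 5, 4)
  X[2, 3] <- NA
  S <- suppressWarnings(rm_from_matrix(X))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_region_matrix(S, f)
  back <- read_region_matrix(f)
  expect_equal(unclass(back), unclass(S), tolerance = 1e-11,
               ignore_attr = TRUE)
  expect_equal(attr(back, "subject_ids"), attr(S, "subject_ids"))
  expect_equal(attr(back, "region_labels"), attr(S, "region_labels"))
  expect_equal(attr(back, "statistic"), attr(S, "statistic"))
})

test_that("tidy and glance views agree with the matrix", {
  X <- matrix(1:6, 3, 2)
  S <- rm_from_matrix(X)
  long <- tidy(S)
  expect_equal(nrow(long), 6L)
  expect_equal(long$value, as.vector(X))
  g <- glance(S)
  expect_equal(g$n_regions, 3L)
  expect_equal(g$n_subjects, 2L)
  expect_equal(g$max, 6)
})
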