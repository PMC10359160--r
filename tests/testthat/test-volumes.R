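test_that("grid and volume constructors enforce their invariants", {
  expect_error(volume_grid(c(4, 4, 4), spacing = c(0, 1, 1)), "positive")
  expect_error(volume_grid(c(1, 4, 4)), ">= 2")
  expect_error(scalar_volume(array(c(1, NA), c(2, 1, 1)) * 1,
                             grid = volume_grid(c(2, 2, 2))), "shape")
  expect_error(scalar_volume(array(NaN, c(2, 2, 2))), "finite")
  expect_error(displacement_field(array(0, c(4, 4, 4, 2))), "3 components")
})

test_that("volume NIfTI round trip preserves values and geometry", {
  set.seed(11)
  vol <- random_volume(c(7, 6, 5), spacing = c(2.5, 2.5, 2.5))
  vol$grid$origin <- c(-10, 5, 2)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$values, vol$values)
  expect_equal(back$grid$spacing, vol$grid$spacing)
  expect_equal(back$grid$origin, vol$grid$origin)
})

test_that("reader rejects non-3D payloads and missing files", {
  set.seed(12)
  expect_error(read_volume(tempfile(fileext = ".nii")), "no such file")
  dvf <- displacement_field(array(rnorm(4^3 * 3), c(4, 4, 4, 3)))
  path <- tempfile(fileext = ".nii.gz")
  write_dvf(dvf, path)
  expect_error(read_volume(path), "3D")
  back <- read_dvf(path)
  expect_equal(back$vectors, dvf$vectors)
  expect_error(read_dvf(tempfile()), "no such file")
})

test_that("file spacing metadata passes through the affine", {
  vol <- scalar_volume(array(0, c(4, 4, 4)), spacing = c(2.5, 2.5, 2.5))
  path <- tempfile(fileext = ".nii")
  write_volume(vol, path)
  expect_equal(read_volume(path)$grid$spacing, c(2.5, 2.5, 2.5))
})

test_that("write_volume refuses an unwritable destination", {
  vol <- scalar_volume(array(0, c(2, 2, 2)))
  expect_error(write_volume(vol, file.path(tempfile(), "x", "v.nii")),
               "does not exist")
})

test_that("mask round trip is exact", {
  set.seed(13)
  m <- random_small_mask()
  path <- tempfile(fileext = ".nii.gz")
  write_mask(m, path)
  expect_equal(read_mask(path)$values, m$values)
})

test_that("resampling to the same spacing is the identity", {
  set.seed(14)
  vol <- random_volume(c(9, 8, 7))
  out <- resample(vol, vol$grid$spacing)
  expect_equal(out$values, vol$values, tolerance = 1e-10)
})

test_that("resampling a constant volume gives a constant at any spacing", {
  vol <- scalar_volume(array(42, c(8, 8, 8)), spacing = c(2, 2, 2))
  out <- resample(vol, c(0.7, 1.3, 2.9))
  expect_true(all(abs(out$values - 42) < 1e-12))
  expect_equal(out$grid$spacing, c(0.7, 1.3, 2.9))
})

test_that("2x finer resampling of a linear ramp interpolates midpoints exactly", {
  n <- 9
  ramp <- array(rep(seq_len(n), times = n * n), c(n, n, n)) # ramp along x
  vol <- scalar_volume(ramp, spacing = c(2, 2, 2))
  out <- resample(vol, c(1, 2, 2))
  # odd output samples coincide with input samples; even ones are midpoints
  expect_equal(out$values[seq(1, 2 * n - 1, 2), 1, 1], as.numeric(seq_len(n)))
  mids <- (seq_len(n - 1) + seq(2, n)) / 2
  expect_equal(out$values[seq(2, 2 * n - 2, 2), 1, 1], mids)
  # physical extent preserved
  expect_equal((dim(out$values) - 1) * out$grid$spacing,
               (n - 1) * vol$grid$spacing)
})

test_that("resample validates spacing", {
  set.seed(20)
  vol <- random_volume()
  expect_error(resample(vol, c(-1, 1, 1)), "positive")
})

test_that("warping with the zero field is the identity, bit-exact", {
  set.seed(15)
  vol <- random_volume(c(6, 7, 8))
  u <- zero_displacement(vol$grid)
  expect_identical(warp(vol, u, "linear")$values, vol$values)
  expect_identical(warp(vol, u, "nearest")$values, vol$values)
})

test_that("one-voxel translation with nearest interpolation shifts the grid", {
  set.seed(16)
  vol <- random_volume(c(6, 6, 6), spacing = c(2, 2, 2))
  vec <- array(0, c(6, 6, 6, 3))
  vec[, , , 1] <- 2      # +1 voxel along x, in mm
  out <- warp(vol, displacement_field(vec, grid = vol$grid), "nearest")
  expect_equal(out$values[1:5, , ], vol$values[2:6, , ])
  expect_equal(out$values[6, , ], vol$values[6, , ])  # replicate boundary
})

test_that("warping a linear ramp with an analytic field matches the closed form", {
  g <- volume_grid(c(12, 12, 12), spacing = c(2, 2, 2))
  co <- grid_coordinates(g)
  ramp <- scalar_volume(3 + 0.5 * co$x, grid = g)
  ctr <- c(11, 11, 11)
  bump <- 3 * exp(-((co$x - ctr[1])^2 + (co$y - ctr[2])^2 +
                    (co$z - ctr[3])^2) / 50)
  vec <- array(0, c(g$shape, 3))
  vec[, , , 1] <- bump
  out <- warp(ramp, displacement_field(vec, grid = g), "linear")
  # a linear function is reproduced exactly by trilinear interpolation
  expected <- 3 + 0.5 * pmin(co$x + bump, max(co$x))
  expect_equal(out$values, expected, tolerance = 1e-12)
})

test_that("warp round trip of an integer translation restores the interior", {
  set.seed(17)
  vol <- random_volume(c(8, 8, 8), spacing = c(1, 1, 1))
  mk <- function(d) {
    vec <- array(0, c(8, 8, 8, 3))
    vec[, , , 1] <- d
    displacement_field(vec, grid = vol$grid)
  }
  once <- warp(vol, mk(2), "nearest")
  back <- warp(once, mk(-2), "nearest")
  expect_equal(back$values[3:8, , ], vol$values[3:8, , ])
})

test_that("warp requires matching grids", {
  set.seed(18)
  vol <- random_volume(c(6, 6, 6))
  u <- zero_displacement(volume_grid(c(6, 6, 6), spacing = c(1, 1, 1)))
  expect_error(warp(vol, u), "same grid")
})

test_that("overlapping z range matches a brute-force slice scan", {
  g <- volume_grid(c(4, 4, 64), spacing = c(2.5, 2.5, 2.5))
  mk <- function(zlo, zhi) {
    v <- array(FALSE, g$shape)
    v[2:3, 2:3, zlo:zhi] <- TRUE
    binary_mask(v, grid = g)
  }
  a <- mk(1, 41)
  b <- mk(21, 61)
  expect_equal(overlapping_z_range(a, b), c(21, 41))
  expect_equal(overlapping_z_range(b, a), c(21, 41))  # symmetric
  expect_equal(overlapping_z_range(a, a), c(1, 41))
  expect_equal(overlapping_z_range(mk(1, 10), mk(40, 60)), integer(0))
})

test_that("interpolation hull brackets warped values", {
  set.seed(19)
  vol <- random_volume(c(10, 10, 10))
  v <- random_smooth_velocity(vol$grid, max_mm = 6)
  u <- integrate_velocity(v, 5)
  out <- warp(vol, u, "linear")
  h <- interpolation_hull(vol, u)
  expect_true(all(out$values >= h$lo$values - 1e-9))
  expect_true(all(out$values <= h$hi$values + 1e-9))
})
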