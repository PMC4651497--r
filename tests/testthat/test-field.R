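dims <- c(12, 10, 8)
sp <- c(2, 2, 2)

test_that("zero-field resampling is an exact identity for nearest, tight for linear", {
  v <- sq_volume(array(rnorm(prod(dims)), dims), sp)
  f0 <- zero_field(dims, sp)
  expect_identical(apply_displacement(v, f0, "nearest")$data, v$data)
  expect_equal(apply_displacement(v, f0, "linear")$data, v$data, tolerance = 1e-12)
})

test_that("constant one-voxel shift matches the brute-force index-shift oracle", {
  v <- sq_volume(array(rnorm(prod(dims)), dims), sp)
  f <- constant_field(dims, c(sp[1], 0, 0), sp)   # +1 voxel along x
  out <- apply_displacement(v, f, "nearest", fill = -99)
  expected <- array(-99, dims)
  expected[1:(dims[1] - 1), , ] <- v$data[2:dims[1], , ]
  expect_identical(out$data, expected)
})

test_that("out-of-domain samples take the fill value exactly", {
  v <- sq_volume(array(1, dims), sp)
  f <- constant_field(dims, c(1000, 0, 0), sp)
  out <- apply_displacement(v, f, "linear", fill = 0)
  expect_true(all(out$data == 0))
})

test_that("linear interpolation of a mask volume is refused", {
  m <- sq_volume(array(TRUE, dims), sp, type = "mask")
  f <- zero_field(dims, sp)
  expect_error(apply_displacement(m, f, "linear"), "mask")
  expect_silent(apply_displacement(m, f, "nearest"))
})

test_that("mask resampling preserves binarity and pairwise disjointness", {
  d32 <- c(24, 24, 24)
  half <- array(FALSE, d32); half[1:12, , ] <- TRUE
  other <- array(FALSE, d32); other[13:24, , ] <- TRUE
  seg_masks <- list(sq_volume(half, sp, type = "mask"),
                    sq_volume(other, sp, type = "mask"))
  f <- random_smooth_field(d32, spacing = sp, amplitude_mm = 2,
                           smoothness_mm = 8, seed = 4)
  res <- lapply(seg_masks, apply_displacement, field = f,
                interpolation = "nearest", fill = 0)
  expect_type(res[[1]]$data, "logical")
  expect_false(any(res[[1]]$data & res[[2]]$data))
})

test_that("field composition has the zero field as identity and adds translations", {
  f <- random_smooth_field(dims, spacing = sp, amplitude_mm = 1,
                           smoothness_mm = 6, seed = 2)
  z <- zero_field(dims, sp)
  expect_equal(compose_fields(z, f)$vectors, f$vectors, tolerance = 1e-12)
  expect_equal(compose_fields(f, z)$vectors, f$vectors, tolerance = 1e-12)
  a <- constant_field(dims, c(2, 0, -2), sp)
  b <- constant_field(dims, c(-1, 3, 1), sp)
  ab <- compose_fields(a, b)
  # constant shifts compose additively away from the border
  expect_equal(ab$vectors[3:9, 3:8, 3:6, ],
               constant_field(dims, c(1, 3, -1), sp)$vectors[3:9, 3:8, 3:6, ])
  expect_error(compose_fields(f, zero_field(c(4, 4, 4), sp)), "mismatch")
})

test_that("composed field equals two-step resampling up to interpolation error", {
  d32 <- c(32, 32, 32)
  # a smooth test volume: interpolation error of composition stays small
  g <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  smooth_v <- array(sin(g$x / 5) * cos(g$y / 7) + g$z / 32, d32)
  v <- sq_volume(smooth_v, sp)
  f <- random_smooth_field(d32, spacing = sp, amplitude_mm = 1.5,
                           smoothness_mm = 8, seed = 5)
  h <- random_smooth_field(d32, spacing = sp, amplitude_mm = 1.5,
                           smoothness_mm = 8, seed = 6)
  one_step <- apply_displacement(v, compose_fields(f, h), "linear")
  two_step <- apply_displacement(apply_displacement(v, h, "linear"), f, "linear")
  core <- 5:28
  expect_lt(max(abs(one_step$data[core, core, core] -
                    two_step$data[core, core, core])), 0.02)
})

test_that("field inversion recovers translations and smooth fields", {
  z <- zero_field(dims, sp)
  expect_equal(invert_field(z)$vectors, z$vectors)
  d32 <- c(32, 32, 32)
  f <- random_smooth_field(d32, spacing = sp, amplitude_mm = 1,
                           smoothness_mm = 6, seed = 5)
  fi <- invert_field(f, max_iter = 100)
  resid <- max(abs(compose_fields(f, fi)$vectors)) / min(sp)
  expect_lt(resid, 0.1)
})

test_that("inversion of a constant shift is the negated shift", {
  # constant fields are their own extension beyond the border, so use a
  # moderate shift and check the interior
  f <- constant_field(dims, c(2, -2, 0), sp)
  fi <- invert_field(f, mask = sq_volume(array(TRUE, dims), sp, type = "mask"),
                     tol = 1e-6, max_iter = 200)
  expect_equal(fi$vectors[3:10, 3:8, 2:7, ],
               constant_field(dims, c(-2, 2, 0), sp)$vectors[3:10, 3:8, 2:7, ],
               tolerance = 1e-5)
})

test_that("random field RMS amplitude scales linearly and is seed-stable", {
  d32 <- c(32, 32, 32)
  mask <- full_mask(d32, sp)
  rms <- vapply(c(0.5, 1, 2), function(a) {
    f <- random_smooth_field(d32, spacing = sp, amplitude_mm = a,
                             smoothness_mm = 6, mask = mask, seed = 9)
    mag2 <- f$vectors[, , , 1]^2 + f$vectors[, , , 2]^2 + f$vectors[, , , 3]^2
    sqrt(mean(mag2))
  }, numeric(1))
  expect_equal(rms, c(0.5, 1, 2), tolerance = 1e-8)
  f1 <- random_smooth_field(d32, spacing = sp, amplitude_mm = 1,
                            smoothness_mm = 6, seed = 3)
  f2 <- random_smooth_field(d32, spacing = sp, amplitude_mm = 1,
                            smoothness_mm = 6, seed = 3)
  expect_identical(f1$vectors, f2$vectors)
  f3 <- random_smooth_field(d32, spacing = sp, amplitude_mm = 1,
                            smoothness_mm = 6, seed = 4)
  expect_gt(max(abs(f1$vectors - f3$vectors)), 0)
})

test_that("voxel tracking follows the transform and flags out-of-domain", {
  z <- zero_field(dims, sp)
  tr <- track_voxel(c(3, 4, 5), z)
  expect_equal(tr$position, c(3, 4, 5))
  expect_false(tr$out_of_domain)
  f <- constant_field(dims, c(sp[1], 0, 0), sp)
  tr2 <- track_voxel(c(3, 4, 5), f)
  expect_equal(tr2$index, c(4, 4, 5))
  tr3 <- track_voxel(c(dims[1], 4, 5), f)
  expect_true(tr3$out_of_domain)
  expect_error(track_voxel(c(0, 1, 1), z), "inside the grid")
})

test_that("displacement fields round-trip through 4D NIfTI", {
  f <- random_smooth_field(dims, spacing = sp, amplitude_mm = 1,
                           smoothness_mm = 6, seed = 7)
  path <- tempfile(fileext = ".nii.gz")
  write_field(f, path)
  f2 <- read_field(path)
  expect_equal(f2$vectors, f$vectors, tolerance = 1e-6)
  expect_equal(f2$spacing, f$spacing)
})
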