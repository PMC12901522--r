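test_that("NIfTI round trip preserves values and geometry", {
  v <- random_volume(c(32, 32, 32), seed = 1)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path)
  expect_identical(back$values, v$values)
  expect_equal(back$voxel_size, c(0.25, 0.25, 0.25), tolerance = 1e-6)
  expect_equal(back$origin, v$origin, tolerance = 1e-6)
})

test_that("reading a truncated file raises a format error", {
  v <- random_volume(c(16, 16, 8), seed = 2)
  path <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, path)
  full <- readBin(path, "raw", file.size(path))
  writeBin(full[1:200], path)
  expect_error(read_volume(path), class = "mcdose_format_error")
})

test_that("resampling to the same voxel size is the identity", {
  v <- random_volume(c(12, 10, 8), seed = 3)
  out <- resample_conservative(v, c(0.25, 0.25, 0.25))
  expect_identical(out$values, v$values)
  expect_identical(out$origin, v$origin)
})

test_that("factor-2 downsampling of block-constant data gives exact block means", {
  set.seed(4)
  blocks <- array(runif(4 * 4 * 4), c(4, 4, 4))
  vals <- blocks[rep(1:4, each = 2), rep(1:4, each = 2), rep(1:4, each = 2)]
  v <- mc_volume(vals, voxel_size = c(1, 1, 1))
  out <- resample_conservative(v, c(2, 2, 2))
  expect_equal(dim(out$values), c(4L, 4L, 4L))
  expect_equal(out$values, blocks, tolerance = 1e-12)
})

test_that("resampling conserves the total integral for arbitrary factors", {
  v <- random_volume(c(20, 16, 12), seed = 5, voxel_size = c(0.3, 0.25, 0.5))
  for (target in list(c(0.25, 0.25, 0.25), c(0.7, 0.6, 0.45), c(1.5, 1, 1))) {
    out <- resample_conservative(v, target)
    int_in <- sum(v$values) * prod(v$voxel_size)
    int_out <- sum(out$values) * prod(out$voxel_size)
    expect_lt(abs(int_out - int_in) / abs(int_in), 1e-6)
    # same physical extent
    expect_equal(dim(out$values) * out$voxel_size, dim(v$values) * v$voxel_size,
                 tolerance = 1e-9)
  }
  expect_error(resample_conservative(v, c(100, 100, 100)), "coarser")
})

test_that("central crop retains the documented window", {
  v <- mc_volume(array(as.numeric(seq_len(200 * 200 * 2)), c(200, 200, 2)))
  out <- crop_or_pad_xy(v, 192)
  # 0-based voxels [4, 196) survive per axis
  expect_identical(out$volume$values, v$values[5:196, 5:196, , drop = FALSE])
})

test_that("padding centres the original with exact zeros around it", {
  v <- random_volume(c(100, 100, 3), seed = 6)
  out <- crop_or_pad_xy(v, 192)
  expect_equal(dim(out$volume$values)[1:2], c(192L, 192L))
  expect_identical(out$volume$values[47:146, 47:146, ], v$values[, , ])
  pad_mask <- array(TRUE, c(192, 192, 3))
  pad_mask[47:146, 47:146, ] <- FALSE
  expect_true(all(out$volume$values[pad_mask] == 0))
})

test_that("crop or pad round-trips interior-supported volumes exactly", {
  # support strictly inside the retained window survives crop + restore
  vals <- array(0, c(40, 40, 4))
  vals[15:26, 15:26, ] <- 1 + seq_len(12 * 12 * 4) / 100
  v <- mc_volume(vals)
  cropped <- crop_or_pad_xy(v, 24)
  restored <- restore_xy(cropped$volume, cropped$placement)
  expect_identical(restored$values, vals)

  # padding round-trip is exact for any content
  v2 <- random_volume(c(20, 20, 4), seed = 7)
  padded <- crop_or_pad_xy(v2, 32)
  expect_identical(restore_xy(padded$volume, padded$placement)$values, v2$values)

  # idempotence at the target size
  again <- crop_or_pad_xy(cropped$volume, 24)
  expect_identical(again$volume$values, cropped$volume$values)
})

test_that("scale constants average the per-case normalization factors", {
  mk <- function(ct_max, dose_max) list(
    ct = array(c(ct_max - 1000, -1000), c(2, 1, 1)),
    dose = array(c(dose_max, 0), c(2, 1, 1)))
  single <- compute_scale_constants(list(mk(1800, 2)))
  expect_equal(single$ct_scale, 1800)
  expect_equal(single$dose_scale, 2)

  pairs <- compute_scale_constants(list(mk(1800, 2), mk(1800, 4)))
  expect_equal(pairs$dose_scale, 3) # arithmetic mean of 2 and 4
  expect_error(compute_scale_constants(list(list(ct = array(-1000, c(1, 1, 1)),
                                                 dose = array(0, c(1, 1, 1))))))
})

test_that("scaled calibration volumes land in the expected range", {
  cs <- small_dose_case()
  cases <- lapply(1:3, function(s) {
    noisy <- sample_noisy_dose(cs$dose, 1.5e6, seed = s)
    list(ct = cs$phantom$hu, dose = noisy$values)
  })
  sc <- compute_scale_constants(cases)
  frac_ok <- mean(vapply(cases, function(ca) {
    scaled <- c((ca$ct + 1000) / sc$ct_scale, ca$dose / sc$dose_scale)
    mean(scaled >= 0 & scaled <= 1.5)
  }, numeric(1)))
  expect_gte(frac_ok, 0.99)
})

test_that("power-of-two scaling round-trips bit-exactly", {
  cs <- small_dose_case()
  sc <- compute_scale_constants(list(list(ct = cs$phantom$hu, dose = cs$dose$values)))
  x <- cs$dose$values
  m <- asNamespace("mcdose")
  expect_identical(m$unscale_dose(m$scale_dose(x, sc), sc), x)
  expect_gte(sc$dose_scale_pow2, sc$dose_scale)
  expect_lt(sc$dose_scale_pow2, 2 * sc$dose_scale)
})
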