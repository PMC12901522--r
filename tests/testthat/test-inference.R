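test_that("patch layouts are minimal, anchored and covering", {
  one <- plan_patches(64, 64)
  expect_identical(one$corners, 0L)
  expect_identical(one$pad_z, 0L)

  short <- plan_patches(16, 64)
  expect_identical(short$corners, 0L)
  expect_identical(short$pad_z, 48L)

  two <- plan_patches(100, 64)
  expect_identical(two$corners, c(0L, 36L))
  # overlap of the two windows: [36, 64) = 28 slices
  expect_equal(64 - 36, 28)

  set.seed(1)
  for (z in sample(1:500, 60)) {
    lay <- plan_patches(z, 64)
    covered <- logical(max(z, 64))
    for (corner in lay$corners) covered[corner + 1:64] <- TRUE
    expect_true(all(covered[1:z]), label = sprintf("coverage at z=%d", z))
    expect_identical(lay$corners, sort(lay$corners))
    if (z > 64) {
      expect_equal(length(lay$corners), ceiling(z / 64))
      expect_equal(lay$corners[length(lay$corners)], z - 64L)
    }
  }
})

identity_setup <- function(zdim) {
  ph <- generate_phantom(phantom_spec(c(20, 20, max(zdim, 16)),
                                      body_semiaxes = c(2, 2, max(zdim, 16) * 0.1)))
  if (zdim < dim(ph$hu)[3]) {
    ph$hu <- ph$hu[, , 1:zdim, drop = FALSE]
    ph$body_mask <- ph$body_mask[, , 1:zdim, drop = FALSE]
  }
  plan <- random_arc_plan(ph, 3, seed = 5)
  dose <- compute_clean_dose(ph, plan)
  noisy <- sample_noisy_dose(dose, 1.5e6, seed = 9)
  scales <- compute_scale_constants(list(list(ct = ph$hu, dose = dose$values)))
  list(ph = ph, noisy = noisy, scales = scales,
       hu = mc_volume(ph$hu, ph$voxel_size, ph$origin))
}

test_that("the identity network makes the full chain exactly invertible", {
  cfg <- unet_config(base_width = 2, xy_size = 24, z_size = 8, levels = 2)
  idnet <- make_identity_network(cfg)
  for (zdim in c(4, 8, 13, 25)) {
    s <- identity_setup(zdim)
    den <- denoise_volume(idnet, s$noisy, s$hu, s$scales, s$ph$body_mask)
    expect_identical(den$values[s$ph$body_mask], s$noisy$values[s$ph$body_mask],
                     label = sprintf("body voxels at z=%d", zdim))
    expect_true(all(den$values[!s$ph$body_mask] == 0))
  }
})

test_that("a volume fitting one patch matches the patched path bit-wise", {
  cfg <- unet_config(base_width = 2, xy_size = 24, z_size = 8, levels = 2)
  net <- build_network(cfg, seed = 13)
  s <- identity_setup(8)
  den <- denoise_volume(net, s$noisy, s$hu, s$scales, s$ph$body_mask)

  # brute-force single pass: scale, pad, run, unscale (no patch logic)
  m <- asNamespace("mcdose")
  dv <- m$scale_dose(s$noisy$values, s$scales)
  cv <- m$scale_ct(s$hu$values, s$scales)
  cp_d <- crop_or_pad_xy(mc_volume(dv), 24)$volume$values
  cp_c <- crop_or_pad_xy(mc_volume(cv), 24)$volume$values
  x <- array(0, c(24, 24, 8, 2)); x[, , , 1] <- cp_d; x[, , , 2] <- cp_c
  y <- unet_forward(net, x)
  y <- array(y, dim(y)[1:3])
  restored <- restore_xy(y, crop_or_pad_xy(mc_volume(dv), 24)$placement)
  restored <- m$unscale_dose(restored, s$scales)
  restored[restored < 0] <- 0
  restored[!s$ph$body_mask] <- 0
  expect_identical(den$values, restored)
})

test_that("overlapping voxels are the arithmetic mean of patch predictions", {
  cfg <- unet_config(base_width = 2, xy_size = 24, z_size = 8, levels = 2)
  net <- build_network(cfg, seed = 17)
  set.seed(3)
  d <- c(24, 24, 13) # two patches at corners 0 and 5, overlap 3
  noisy <- mc_volume(array(runif(prod(d)), d))
  hu <- mc_volume(array(0, d))
  mask <- array(TRUE, d)
  scales <- compute_scale_constants(list(list(ct = hu$values, dose = noisy$values)))
  den <- denoise_volume(net, noisy, hu, scales, mask)

  m <- asNamespace("mcdose")
  dv <- m$scale_dose(noisy$values, scales)
  cv <- m$scale_ct(hu$values, scales)
  run_patch <- function(zs) {
    x <- array(0, c(24, 24, 8, 2))
    x[, , , 1] <- dv[, , zs]; x[, , , 2] <- cv[, , zs]
    array(unet_forward(net, x), c(24, 24, 8))
  }
  lay <- plan_patches(13, 8)
  expect_identical(lay$corners, c(0L, 5L))
  y1 <- run_patch(1:8)
  y2 <- run_patch(6:13)
  assembled <- array(0, d)
  assembled[, , 1:5] <- y1[, , 1:5]
  assembled[, , 6:8] <- (y1[, , 6:8] + y2[, , 1:3]) / 2
  assembled[, , 9:13] <- y2[, , 4:8]
  assembled <- m$unscale_dose(assembled, scales)
  assembled[assembled < 0] <- 0
  expect_equal(den$values, assembled, tolerance = 1e-12)
})

test_that("plan denoising sums fields before a single pass", {
  cfg <- unet_config(base_width = 2, xy_size = 24, z_size = 8, levels = 2)
  net <- build_network(cfg, seed = 19)
  s <- identity_setup(8)
  f1 <- s$noisy
  f2 <- mc_volume(0.5 * s$noisy$values, f1$voxel_size, f1$origin)
  whole <- mc_volume(f1$values + f2$values, f1$voxel_size, f1$origin)

  single <- denoise_volume(net, whole, s$hu, s$scales, s$ph$body_mask)
  planned <- denoise_plan(net, list(f1, f2), s$hu, s$scales, s$ph$body_mask)
  expect_identical(planned$values, single$values)
  # field order does not matter
  expect_identical(denoise_plan(net, list(f2, f1), s$hu, s$scales, s$ph$body_mask)$values,
                   planned$values)
  # two half-weight copies equal the single full field
  h1 <- mc_volume(whole$values / 2, f1$voxel_size, f1$origin)
  expect_identical(denoise_plan(net, list(h1, h1), s$hu, s$scales, s$ph$body_mask)$values,
                   planned$values)
  expect_error(denoise_plan(net, list(), s$hu, s$scales, s$ph$body_mask), "empty")
})
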