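test_that("gamma of a distribution against itself is zero everywhere", {
  ref <- smooth_dose_volume(seed = 1)
  res <- gamma_map(ref, ref, gamma_criteria(2, 2))
  expect_equal(res$pass_rate, 100)
  expect_true(all(res$gamma[!is.na(res$gamma)] < 1e-9))
  expect_gt(res$n_evaluated, 0)
  # gamma is only evaluated at or above the 10% threshold
  expect_true(all(is.na(res$gamma[ref$values < 0.1 * max(ref$values)])))
})

test_that("a uniform +2% offset sits exactly on the 2%/2mm boundary", {
  ref <- mc_volume(array(1, c(12, 12, 8)))
  ev <- mc_volume(array(1.02, c(12, 12, 8)))
  res <- gamma_map(ref, ev, gamma_criteria(2, 2))
  expect_equal(res$pass_rate, 100)
  expect_equal(max(res$gamma, na.rm = TRUE), 1, tolerance = 1e-6)
  # tighter dose criterion fails the same offset
  res1 <- gamma_map(ref, ev, gamma_criteria(1, 2))
  expect_equal(res1$pass_rate, 0)
})

test_that("optimized gamma equals the exhaustive oracle on random pairs", {
  crit <- gamma_criteria(2, 2)
  for (seed in 1:3) {
    d <- c(16, 16, 16)
    set.seed(seed + 100)
    c0 <- (d + 1) / 2 + runif(3, -2, 2)
    w <- runif(3, 1.8, 2.8)
    bump <- outer(outer(exp(-((seq_len(d[1]) - c0[1]) / w[1])^2),
                        exp(-((seq_len(d[2]) - c0[2]) / w[2])^2)),
                  exp(-((seq_len(d[3]) - c0[3]) / w[3])^2))
    ref <- mc_volume(bump + 0.01 * array(runif(prod(d)), d))
    ev <- mc_volume(ref$values * (1 + rnorm(length(ref$values), 0, 0.02)) +
                      0.005 * array(runif(length(ref$values)), dim(ref$values)))
    res <- gamma_map(ref, ev, crit)
    orc <- gamma_oracle(ref, ev, crit)
    ok <- !is.na(res$gamma)
    expect_identical(ok, !is.na(orc$gamma))
    expect_lt(max(abs(res$gamma[ok] - orc$gamma[ok])), 0.01)
    expect_lt(abs(res$pass_rate - orc$pass_rate), 0.5)
  }
})

test_that("tighter criteria never pass more voxels", {
  for (seed in 5:8) {
    ref <- smooth_dose_volume(seed = seed)
    ev <- sample_noisy_dose(ref, 5e7, seed = seed)
    g2 <- gamma_map(ref, ev, gamma_criteria(2, 2, max_gamma = 1.5))$pass_rate
    g3 <- gamma_map(ref, ev, gamma_criteria(3, 3, max_gamma = 1.5))$pass_rate
    expect_lte(g2, g3)
  }
})

test_that("capping the gamma search preserves classification", {
  ref <- smooth_dose_volume(seed = 11)
  ev <- sample_noisy_dose(ref, 2e7, seed = 3)
  full <- gamma_map(ref, ev, gamma_criteria(2, 2))
  capped <- gamma_map(ref, ev, gamma_criteria(2, 2, max_gamma = 1.2))
  expect_equal(capped$pass_rate, full$pass_rate)
  ok <- !is.na(full$gamma) & full$gamma <= 1.2
  expect_equal(capped$gamma[ok], full$gamma[ok], tolerance = 1e-12)
})

test_that("masked RMSE matches its direct definition", {
  ref <- smooth_dose_volume(seed = 21)
  expect_equal(rmse_masked(ref, ref), 0)

  shifted <- mc_volume(ref$values + 0.037, ref$voxel_size, ref$origin)
  expect_equal(rmse_masked(ref, shifted), 0.037, tolerance = 1e-12)

  set.seed(22)
  ev <- mc_volume(ref$values + rnorm(length(ref$values), 0, 0.01),
                  ref$voxel_size, ref$origin)
  mask <- ref$values > 0.10 * max(ref$values)
  naive <- sqrt(sum((ev$values[mask] - ref$values[mask])^2) / sum(mask))
  expect_equal(rmse_masked(ref, ev), naive)
  # the all-voxel variant is the threshold-0 option
  expect_equal(rmse_masked(ref, ev, threshold_fraction = 0),
               sqrt(mean((ev$values[ref$values > 0] - ref$values[ref$values > 0])^2)))
})

test_that("whole-treatment RMSE reproduces the worked example", {
  expect_equal(round(whole_treatment_rmse(1.19e-4, 300, 50.0, 2.0), 1), 0.9)
  expect_equal(whole_treatment_rmse(0, 300, 50, 2), 0)
  expect_equal(whole_treatment_rmse(2e-4, 150, 2, 2), 2e-4 * 150)
  expect_error(whole_treatment_rmse(1e-4, 300, 50, 0))
})

test_that("ISNR is the decibel MSE ratio", {
  ref <- smooth_dose_volume(seed = 31)
  noisy <- sample_noisy_dose(ref, 1e6, seed = 1)
  expect_equal(isnr(noisy, noisy, ref), 0)

  resid <- noisy$values - ref$values
  den10 <- mc_volume(ref$values + resid / sqrt(10), ref$voxel_size, ref$origin)
  expect_equal(isnr(noisy, den10, ref), 10, tolerance = 1e-9)
  den100 <- mc_volume(ref$values + resid / 10, ref$voxel_size, ref$origin)
  expect_equal(isnr(noisy, den100, ref), 20, tolerance = 1e-9)
  expect_error(isnr(noisy, ref, ref), class = "mcdose_unbounded_isnr")
})

test_that("DVH curves step, ramp and bound correctly", {
  mask <- array(TRUE, c(10, 10, 1))
  uniform <- mc_volume(array(5, c(10, 10, 1)))
  cu <- dvh(uniform, mask, bin_width = 0.5)
  expect_equal(cu$volume[1], 100)
  expect_true(all(diff(cu$volume) <= 0))
  expect_true(all(cu$volume[cu$dose <= 5] == 100))
  expect_true(all(cu$volume[cu$dose > 5] == 0))
  expect_equal(dose_at_volume(cu, 98), 5, tolerance = 0.5)
  expect_equal(dose_at_volume(cu, 2), 5, tolerance = 0.5)
  expect_equal(cu$mean_dose, 5)

  ramp <- mc_volume(array(seq(0, 10, length.out = 1000), c(10, 10, 10)))
  maskr <- array(TRUE, c(10, 10, 10))
  cr <- dvh(ramp, maskr, bin_width = 0.01)
  expect_equal(cr$volume[1], 100)
  expect_equal(dose_at_volume(cr, 50), 5, tolerance = 0.02)
  # V(d) is linear in d for a volume-uniform ramp
  mid <- cr$dose > 1 & cr$dose < 9
  fit <- lm(cr$volume[mid] ~ cr$dose[mid])
  expect_equal(unname(coef(fit)[2]), -10, tolerance = 0.01)

  # quantile ordering holds for arbitrary distributions
  set.seed(5)
  arb <- mc_volume(array(rgamma(500, 2, 1), c(10, 10, 5)))
  ca <- dvh(arb, array(TRUE, c(10, 10, 5)), bin_width = 0.01)
  d98 <- dose_at_volume(ca, 98); d50 <- dose_at_volume(ca, 50); d2 <- dose_at_volume(ca, 2)
  expect_lte(d98, d50)
  expect_lte(d50, d2)

  # volume_at_dose agrees with the curve on its own grid
  expect_equal(volume_at_dose(arb, array(TRUE, c(10, 10, 5)), ca$dose[50]),
               ca$volume[50])
  expect_error(dvh(uniform, array(FALSE, c(10, 10, 1))), "empty")
  expect_error(dose_at_volume(cu, 0))
})

test_that("evaluation surfaces tidy summaries", {
  ref <- smooth_dose_volume(seed = 41)
  res <- gamma_map(ref, ref, gamma_criteria(3, 3))
  g <- glance(res)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$pass_rate, 100)

  cu <- dvh(ref, array(TRUE, dim(ref$values)), bin_width = 0.01, label = "body")
  td <- tidy(cu)
  expect_s3_class(td, "tbl_df")
  expect_identical(names(td), c("structure", "dose", "volume"))
  expect_s3_class(autoplot(cu), "ggplot")
})
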