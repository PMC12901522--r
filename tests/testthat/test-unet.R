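test_that("closed-form parameter count matches instantiated networks", {
  cfgs <- list(
    unet_config(base_width = 2, xy_size = 12, z_size = 4, levels = 2),
    unet_config(base_width = 3, xy_size = 24, z_size = 8, levels = 3,
                in_channels = 1),
    unet_config(base_width = 2, xy_size = 12, z_size = 4, levels = 2,
                batch_norm = TRUE),
    unet_config(base_width = 4, xy_size = 48, z_size = 16))
  for (cfg in cfgs) {
    net <- build_network(cfg, seed = 1)
    expect_identical(network_parameters(net), count_parameters(cfg))
  }
})

test_that("layer descriptors use the convolutional closed forms", {
  spec <- network_spec(unet_config(base_width = 2, xy_size = 12, z_size = 4,
                                   levels = 2))
  first <- spec[spec$layer == "enc1.conv1", ]
  # 3x3x3 convolution, 2 -> 2 channels: 2*2*27 weights + 2 biases
  expect_equal(first$params, 2 * 2 * 27 + 2)
  final <- spec[spec$layer == "final", ]
  expect_equal(final$params, 2 * 1 + 1)
  up <- spec[spec$layer == "up1", ]
  # transposed convolution with kernel = stride (3,3,1): in*out*9 + out
  expect_equal(up$params, 4 * 2 * 9 + 2)
})

test_that("the production configuration carries 2.2578e7 parameters", {
  expect_identical(count_parameters(unet_config()), 22578241)
  expect_equal(round(count_parameters(unet_config()) / 1e7, 4), 2.2578)
})

test_that("doubling all channel widths roughly quadruples the count", {
  base <- unet_config(base_width = 8)
  doubled <- unet_config(base_width = 16)
  ratio <- count_parameters(doubled) / count_parameters(base)
  expect_gte(ratio, 3.6)
  expect_lte(ratio, 4.0)
})

test_that("indivisible input extents are rejected with the offending axis", {
  expect_error(unet_config(xy_size = 50), class = "mcdose_config_error")
  expect_error(unet_config(xy_size = 50), "axis x")
  expect_error(unet_config(z_size = 10), "axis z")
  expect_error(unet_config(z_size = 10), "level")
})

test_that("all five candidate configurations are constructible", {
  cands <- unet_candidates()
  expect_length(cands, 5)
  expect_identical(cands$model2$z_size, 64L)
  expect_identical(cands$model4$in_channels, 1L)
  expect_true(cands$model5$batch_norm)
  for (cfg in cands) expect_s3_class(cfg, "mc_unet_config")
  # z sizes 32, 64, 96 all satisfy the pooling divisibility: the first
  # pool has z-stride 1, so z must be divisible by 2^3 = 8
  for (z in c(32, 64, 96)) expect_silent(unet_config(z_size = z))
})

test_that("forward pass honours the shape contract and is deterministic", {
  cfg <- unet_config(base_width = 2, xy_size = 24, z_size = 8, levels = 3)
  net <- build_network(cfg, seed = 3)
  x <- array(runif(24 * 24 * 8 * 2), c(24, 24, 8, 2))
  y1 <- unet_forward(net, x)
  y2 <- unet_forward(net, x)
  expect_identical(dim(y1), c(24L, 24L, 8L, 1L))
  expect_identical(y1, y2)
  expect_error(unet_forward(net, array(0, c(24, 24, 8, 1))), "channels")

  zeros <- unet_forward(net, array(0, c(24, 24, 8, 2)))
  expect_identical(dim(zeros), c(24L, 24L, 8L, 1L))
})

test_that("batch normalization appears exactly when configured", {
  with_bn <- build_network(unet_config(base_width = 2, xy_size = 12, z_size = 4,
                                       levels = 2, batch_norm = TRUE), seed = 1)
  without <- build_network(unet_config(base_width = 2, xy_size = 12, z_size = 4,
                                       levels = 2), seed = 1)
  expect_true(any(grepl("bn", names(with_bn$params))))
  expect_false(any(grepl("bn", names(without$params))))
  expect_true(any(network_spec(with_bn$config)$kind == "batchnorm"))
})

test_that("backpropagation matches central finite differences", {
  set.seed(42)
  cfg <- unet_config(base_width = 2, xy_size = 12, z_size = 4, levels = 2)
  net <- build_network(cfg, seed = 7)
  # biases moved off zero so no pre-activation sits exactly on a ReLU kink
  for (nm in grep("[.]b$", names(net$params), value = TRUE))
    net$params[[nm]] <- rnorm(length(net$params[[nm]]), 0, 0.05)
  x <- array(runif(12 * 12 * 4 * 2), c(12, 12, 4, 2))
  tgt <- array(runif(12 * 12 * 4), c(12, 12, 4, 1))
  loss_at <- function(params) {
    n2 <- net; n2$params <- params
    sum((unet_forward(n2, x) - tgt)^2)
  }
  y <- unet_forward(net, x, keep_cache = TRUE)
  grads <- unet_backward(net, y, 2 * (unclass(y) - tgt))
  eps <- 1e-6
  for (nm in names(net$params)) {
    for (trial in 1:3) {
      i <- sample(length(net$params[[nm]]), 1)
      pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("the identity construction reproduces channel 1 exactly", {
  cfg <- unet_config(base_width = 2, xy_size = 24, z_size = 8, levels = 2)
  idnet <- make_identity_network(cfg)
  x <- array(runif(24 * 24 * 8 * 2), c(24, 24, 8, 2))
  y <- unet_forward(idnet, x)
  expect_identical(array(y, dim(y)[1:3]), x[, , , 1])
})

test_that("checkpoints round-trip weights and verify the fingerprint", {
  cfg <- unet_config(base_width = 2, xy_size = 12, z_size = 4, levels = 2)
  net <- build_network(cfg, seed = 5)
  dir <- withr::local_tempdir()
  save_checkpoint(net, dir)
  back <- load_checkpoint(dir)
  expect_identical(back$params, net$params)
  expect_true(file.exists(file.path(dir, "architecture.json")))
})
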