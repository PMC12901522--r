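test_that("case splits follow the rounding rule and stay disjoint", {
  s29 <- split_by_case(1:29, seed = 3)
  expect_length(s29$train, 23)
  expect_length(s29$val, 3)
  expect_length(s29$test, 3)

  s10 <- split_by_case(1:10, seed = 1)
  expect_length(s10$train, 8)
  expect_length(s10$val, 1)
  expect_length(s10$test, 1)

  for (seed in 1:10) {
    s <- split_by_case(letters[1:12], seed = seed)
    all_ids <- c(s$train, s$val, s$test)
    expect_length(all_ids, 12)
    expect_false(any(duplicated(all_ids)))
    expect_setequal(all_ids, letters[1:12])
  }
  expect_identical(split_by_case(1:20, seed = 5), split_by_case(1:20, seed = 5))
  expect_error(split_by_case(1:2), "at least 3")
})

make_triplet <- function(d = c(12, 12, 8), seed = 1) {
  set.seed(seed)
  list(noisy = array(runif(prod(d)), d),
       clean = array(runif(prod(d)), d),
       ct = array(runif(prod(d)), d))
}

test_that("patch sampling draws uniform corners aligned across volumes", {
  tr <- make_triplet(c(16, 16, 128))
  # volume exactly patch-sized: the only window is the whole volume
  whole <- sample_patch(tr, c(16, 16, 128), rng_seed = 1)
  expect_identical(whole$noisy, tr$noisy)
  expect_identical(attr(whole, "corner"), c(0L, 0L, 0L))

  set.seed(2)
  corners <- vapply(1:1000, function(i)
    attr(sample_patch(tr, c(16, 16, 64)), "corner")[3], integer(1))
  expect_identical(range(corners), c(0L, 64L))
  expect_gt(length(unique(corners)), 40)

  p <- sample_patch(tr, c(8, 8, 32), rng_seed = 9)
  corner <- attr(p, "corner")
  sl <- lapply(1:3, function(a) corner[a] + seq_len(c(8, 8, 32)[a]))
  expect_identical(p$clean, tr$clean[sl[[1]], sl[[2]], sl[[3]]])
  expect_identical(p$ct, tr$ct[sl[[1]], sl[[2]], sl[[3]]])
  expect_error(sample_patch(tr, c(32, 8, 8)), "smaller")
})

test_that("geometric augmentation preserves voxel pairing and group structure", {
  tr <- make_triplet(c(10, 10, 6), seed = 3)
  tr$clean <- tr$noisy + 100 # exact voxel correspondence marker

  seeds <- 1:300
  tf_of <- function(s) attr(augment_patch(tr, rng_seed = s), "transform")
  infos <- lapply(seeds, tf_of)
  ks <- vapply(infos, `[[`, integer(1), "k")
  expect_setequal(unique(ks), 0:3)

  for (s in seeds[1:15]) {
    out <- augment_patch(tr, rng_seed = s)
    # the same permutation was applied to all members
    expect_identical(out$clean, out$noisy + 100)
    expect_setequal(as.vector(out$noisy), as.vector(tr$noisy))
  }

  # identity draw exists and acts as identity
  no_flip <- !vapply(infos, function(i) any(i$flips), logical(1))
  id_seed <- seeds[which(ks == 0 & no_flip)][1]
  expect_false(is.na(id_seed))
  expect_identical(augment_patch(tr, rng_seed = id_seed)$noisy, tr$noisy)

  # a quarter turn applied four times returns to the start
  rot_seed <- seeds[which(ks == 1 & no_flip)][1]
  expect_false(is.na(rot_seed))
  v <- tr
  for (i in 1:4) v <- augment_patch(v, rng_seed = rot_seed)
  expect_identical(v$noisy, tr$noisy)

  # odd quarter turns require a square xy footprint
  rect <- make_triplet(c(10, 8, 4))
  expect_error(augment_patch(rect, rng_seed = rot_seed), "square")
})

test_that("summed-squared-error behaves as a sum over voxels", {
  a <- array(1, c(2, 2, 2))
  expect_equal(sse_loss(a, a), 0)
  expect_equal(sse_loss(a + 1, a), 8)
  set.seed(4)
  p <- array(runif(60), c(5, 4, 3))
  q <- array(runif(60), c(5, 4, 3))
  expect_equal(sse_loss(p, q), mean((p - q)^2) * length(p))
  expect_error(sse_loss(p, array(0, c(4, 5, 3))), "mismatch")
})

test_that("plateau scheduler divides the rate after 4 flat epochs", {
  st <- plateau_scheduler(1e-4)
  for (v in c(5, 4, 4, 4, 4, 4)) st <- scheduler_step(st, v)
  # best at epoch 2; four non-improving epochs later the rate drops by 5
  expect_equal(st$lr, 2e-5)
  expect_equal(st$best_epoch, 2L)
  expect_false(st$stop)
  # counter reset: three more flat epochs do not trigger another decay
  for (v in c(4, 4, 4)) st <- scheduler_step(st, v)
  expect_equal(st$lr, 2e-5)
  st <- scheduler_step(st, 4)
  expect_equal(st$lr, 4e-6)
})

test_that("early stopping triggers after 30 epochs without improvement", {
  st <- plateau_scheduler(1e-4)
  st <- scheduler_step(st, 10)
  epoch <- 1L
  while (!st$stop) {
    st <- scheduler_step(st, 10)
    epoch <- epoch + 1L
    expect_lt(epoch, 60) # safety
  }
  expect_equal(st$epoch, 31L)
  expect_equal(st$best_epoch, 1L)
})

test_that("training converges on a small identity task and keeps the best epoch", {
  set.seed(8)
  mk <- function(seed) {
    set.seed(seed)
    v <- array(0, c(12, 12, 8))
    v[4:9, 4:9, 3:6] <- runif(1, 0.5, 1)
    list(noisy = v, clean = v, ct = array(0.5, c(12, 12, 8)))
  }
  data <- list(train = lapply(1:8, mk), val = lapply(9:10, mk))
  cfg <- train_config(initial_lr = 1e-2, patch_size = c(12, 12, 8),
                      max_epochs = 60, seed = 11)
  net <- build_network(unet_config(base_width = 2, xy_size = 12, z_size = 8,
                                   levels = 2), seed = 2)
  fit <- train_network(net, data, cfg)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.10 * h$train_loss[1])
  expect_equal(fit$best_epoch, which.min(h$val_loss))

  # returned weights are the best-validation weights: recomputing the
  # validation loss with them reproduces the recorded minimum
  val_loss <- mean(vapply(data$val, function(p) {
    x <- array(0, c(12, 12, 8, 2))
    x[, , , 1] <- p$noisy; x[, , , 2] <- p$ct
    sse_loss(unet_forward(fit$network, x), array(p$clean, c(12, 12, 8, 1)))
  }, numeric(1)))
  expect_equal(val_loss, fit$best_val_loss, tolerance = 1e-10)
})

test_that("training is reproducible given the seed", {
  mk <- function(seed) make_triplet(c(12, 12, 8), seed)
  data <- list(train = lapply(1:4, mk), val = list(mk(5)))
  cfg <- train_config(patch_size = c(12, 12, 4), max_epochs = 2, seed = 21)
  run <- function() {
    net <- build_network(unet_config(base_width = 2, xy_size = 12, z_size = 4,
                                     levels = 2), seed = 6)
    train_network(net, data, cfg)$history
  }
  expect_identical(run(), run())
})
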