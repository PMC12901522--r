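#' Split cases into train / validation / test sets
#'
#' The split is performed on a case (CT) basis to prevent test leakage:
#' every triplet generated from a case inherits the case's split. Cases are
#' shuffled with a seeded generator; validation and test sizes are
#' `round(n * fraction)` with a minimum of one case each, and the remainder
#' goes to training.
#'
#' @param case_ids Vector of at least 3 unique case identifiers.
#' @param fractions Length-3 numeric summing to 1 (default 0.8/0.1/0.1).
#' @param seed Integer seed.
#' @return A list of class `mc_split` with `train`, `val`, `test` (vectors
#'   of case ids), `fractions` and `seed`.
#' @examples
#' split_by_case(1:29, seed = 7)
#' @export
split_by_case <- function(case_ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  case_ids <- unique(case_ids)
  n <- length(case_ids)
  if (n < 3L) stopf("need at least 3 cases to split")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stopf("`fractions` must be three numbers summing to 1")
  set.seed(as.integer(seed))
  shuffled <- sample(case_ids)
  n_val <- max(1L, round(n * fractions[2]))
  n_test <- max(1L, round(n * fractions[3]))
  if (n_val + n_test >= n) stopf("too few cases for a non-empty training set")
  structure(list(train = shuffled[seq_len(n - n_val - n_test)],
                 val = shuffled[n - n_val - n_test + seq_len(n_val)],
                 test = shuffled[n - n_test + seq_len(n_test)],
                 fractions = fractions, seed = seed),
            class = "mc_split")
}

#' @export
print.mc_split <- function(x, ...) {
  cat(sprintf("<mc_split> %d train / %d val / %d test cases\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Sample an aligned random patch from a noisy/clean/CT triplet
#'
#' One uniformly-random corner, valid for all three volumes, is drawn and
#' the same window is applied to each; the corner is recorded in the
#' `"corner"` attribute.
#'
#' @param triplet List with 3D arrays `noisy`, `clean`, `ct` of a common
#'   shape (each already padded to at least `patch_size`).
#' @param patch_size Length-3 integer patch extent.
#' @param rng_seed Optional seed; if `NULL` the current RNG stream is used.
#' @return List with the three patches and attribute `corner` (0-based).
#' @export
sample_patch <- function(triplet, patch_size, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  d <- dim(triplet$noisy)
  patch_size <- as.integer(patch_size)
  stopifnot(identical(d, dim(triplet$clean)), identical(d, dim(triplet$ct)))
  if (any(d < patch_size))
    stopf("volume %s smaller than patch %s; pad first",
          paste(d, collapse = "x"), paste(patch_size, collapse = "x"))
  corner <- vapply(1:3, function(a) sample.int(d[a] - patch_size[a] + 1L, 1L) - 1L,
                   integer(1))
  slice <- lapply(1:3, function(a) corner[a] + seq_len(patch_size[a]))
  out <- lapply(triplet[c("noisy", "clean", "ct")], function(v)
    v[slice[[1]], slice[[2]], slice[[3]], drop = FALSE])
  attr(out, "corner") <- corner
  out
}

#' Apply random mirroring and 90-degree xy rotation to a patch triplet
#'
#' Independent coin flips decide mirroring along each axis; a rotation by
#' `k * 90` degrees (k in 0..3) is applied in the xy plane about z. The
#' identical transform is applied to all three patches so noisy/clean/CT
#' voxel correspondence is preserved.
#'
#' @param patches List with arrays `noisy`, `clean`, `ct` (square xy
#'   footprint required for odd k).
#' @param rng_seed Optional seed; `NULL` uses the current RNG stream.
#' @param mirror_axes Axes eligible for mirroring (default all three).
#' @return The transformed list, with attribute `transform`.
#' @export
augment_patch <- function(patches, rng_seed = NULL, mirror_axes = 1:3) {
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  d <- dim(patches$noisy)
  flips <- logical(3)
  flips[mirror_axes] <- runif(length(mirror_axes)) < 0.5
  k <- sample(0:3, 1L)
  if (k %% 2L == 1L && d[1] != d[2])
    stopf("odd quarter-turns need a square xy footprint, got %dx%d", d[1], d[2])
  tf <- function(v) {
    if (flips[1]) v <- v[rev(seq_len(dim(v)[1])), , , drop = FALSE]
    if (flips[2]) v <- v[, rev(seq_len(dim(v)[2])), , drop = FALSE]
    if (flips[3]) v <- v[, , rev(seq_len(dim(v)[3])), drop = FALSE]
    if (k > 0) for (q in seq_len(k)) {
      # one quarter turn in the xy plane: transpose xy then reverse x
      v <- aperm(v, c(2L, 1L, 3L))
      v <- v[rev(seq_len(dim(v)[1])), , , drop = FALSE]
    }
    v
  }
  out <- lapply(patches[c("noisy", "clean", "ct")], tf)
  attr(out, "transform") <- list(flips = flips, k = k)
  out
}

#' Summed-squared-error loss
#'
#' @param prediction,target Arrays of identical shape.
#' @return `sum((prediction - target)^2)`.
#' @export
sse_loss <- function(prediction, target) {
  if (!identical(dim(prediction), dim(target)))
    stopf("shape mismatch: %s vs %s", paste(dim(prediction), collapse = "x"),
          paste(dim(target), collapse = "x"))
  sum((prediction - target)^2)
}

#' Training protocol configuration
#'
#' Defaults follow the optimization protocol of the denoiser: Adam at
#' initial learning rate 1e-4, batch size 2, summed-squared-error loss,
#' learning rate divided by 5 after 4 consecutive epochs without validation
#' improvement, early stop after 30 such epochs, random 192x192x64 patches.
#' "Improvement" means a strict relative decrease of the epoch validation
#' loss by more than 1e-8.
#'
#' @param batch_size Samples per optimizer step (default 2).
#' @param initial_lr Initial Adam learning rate (default 1e-4).
#' @param lr_decay_factor Learning-rate division factor on plateau (default 5).
#' @param lr_patience Epochs without improvement before decay (default 4).
#' @param early_stop_patience Epochs without improvement before stopping
#'   (default 30).
#' @param max_epochs Hard epoch cap (default 1000).
#' @param patch_size Length-3 patch extent (default `c(192, 192, 64)`).
#' @param mirror_axes Axes eligible for mirroring augmentation.
#' @param seed Integer seed controlling patch sampling and augmentation.
#' @return A list of class `mc_train_config`.
#' @export
train_config <- function(batch_size = 2, initial_lr = 1e-4, lr_decay_factor = 5,
                         lr_patience = 4, early_stop_patience = 30,
                         max_epochs = 1000, patch_size = c(192, 192, 64),
                         mirror_axes = 1:3, seed = 1L) {
  for (nm in c("batch_size", "initial_lr", "lr_decay_factor", "lr_patience",
               "early_stop_patience", "max_epochs"))
    check_number(get(nm), nm, lower = 0, allow_zero = FALSE)
  structure(list(batch_size = as.integer(batch_size), initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 patch_size = as.integer(patch_size),
                 mirror_axes = mirror_axes, seed = as.integer(seed)),
            class = "mc_train_config")
}

#' Plateau learning-rate scheduler and early-stopping state machine
#'
#' Pure bookkeeping, exposed for direct testing: feed one validation loss
#' per epoch with [scheduler_step()] and read the resulting learning rate,
#' best epoch and stop flag.
#'
#' @param initial_lr,decay_factor,lr_patience,stop_patience Scheduler
#'   parameters (see [train_config()]).
#' @param rel_tol Relative improvement threshold (default 1e-8).
#' @return An environment-free state list; update with [scheduler_step()].
#' @export
plateau_scheduler <- function(initial_lr, decay_factor = 5, lr_patience = 4,
                              stop_patience = 30, rel_tol = 1e-8) {
  list(lr = initial_lr, decay_factor = decay_factor, lr_patience = lr_patience,
       stop_patience = stop_patience, rel_tol = rel_tol,
       best = Inf, best_epoch = 0L, epoch = 0L,
       since_improve_lr = 0L, since_improve_stop = 0L, stop = FALSE)
}

#' @rdname plateau_scheduler
#' @param state Scheduler state.
#' @param val_loss Validation loss of the finished epoch.
#' @export
scheduler_step <- function(state, val_loss) {
  state$epoch <- state$epoch + 1L
  improved <- val_loss < state$best * (1 - state$rel_tol)
  if (improved) {
    state$best <- val_loss
    state$best_epoch <- state$epoch
    state$since_improve_lr <- 0L
    state$since_improve_stop <- 0L
  } else {
    state$since_improve_lr <- state$since_improve_lr + 1L
    state$since_improve_stop <- state$since_improve_stop + 1L
    if (state$since_improve_lr >= state$lr_patience) {
      state$lr <- state$lr / state$decay_factor
      state$since_improve_lr <- 0L # counter resets after each decrease
    }
    if (state$since_improve_stop >= state$stop_patience) state$stop <- TRUE
  }
  state
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) { p[] <- 0; p }),
       v = lapply(params, function(p) { p[] <- 0; p }),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# deterministic central patch used for the per-epoch validation loss
center_patch <- function(triplet, patch_size) {
  d <- dim(triplet$noisy)
  corner <- pmax((d - patch_size) %/% 2L, 0L)
  slice <- lapply(1:3, function(a) corner[a] + seq_len(patch_size[a]))
  lapply(triplet[c("noisy", "clean", "ct")], function(v)
    v[slice[[1]], slice[[2]], slice[[3]], drop = FALSE])
}

stack_channels <- function(noisy, ct, in_channels) {
  d <- dim(noisy)
  if (in_channels == 1L) {
    out <- noisy; dim(out) <- c(d, 1L)
  } else {
    out <- array(0, c(d, 2L))
    out[, , , 1L] <- noisy
    out[, , , 2L] <- ct
  }
  out
}

#' Train the U-net denoiser
#'
#' Runs the full optimization protocol: one random (augmented) patch per
#' training triplet per epoch, Adam updates on batches of
#' `config$batch_size`, per-epoch validation loss on deterministic central
#' patches, plateau learning-rate decay, early stopping, and best-epoch
#' checkpointing (the returned weights are those of the epoch with the
#' lowest validation loss, not the last epoch).
#'
#' @param network An `mc_unet` (weights are the starting point).
#' @param data List with `train` and `val`, each a list of triplets
#'   `list(noisy, clean, ct)` of scaled 3D arrays.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch?
#' @return A list of class `mc_unet_fit`: `network` (best weights),
#'   `history` (tibble: epoch, train_loss, val_loss, lr), `best_epoch`,
#'   `best_val_loss`.
#' @export
train_network <- function(network, data, config = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(network, "mc_unet"), inherits(config, "mc_train_config"))
  if (length(data$train) < 1L || length(data$val) < 1L)
    stopf("need non-empty train and val sets")
  in_ch <- network$config$in_channels
  ps <- config$patch_size
  opt <- adam_init(network$params)
  sched <- plateau_scheduler(config$initial_lr, config$lr_decay_factor,
                             config$lr_patience, config$early_stop_patience)
  best_params <- network$params
  history <- list()
  set.seed(config$seed)

  val_patches <- lapply(data$val, center_patch, patch_size = ps)

  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- sample(length(data$train))
    epoch_loss <- 0
    n_seen <- 0L
    batch_grads <- NULL
    batch_count <- 0L
    for (ti in order_idx) {
      patch <- augment_patch(sample_patch(data$train[[ti]], ps),
                             mirror_axes = config$mirror_axes)
      x <- stack_channels(patch$noisy, patch$ct, in_ch)
      y <- unet_forward(network, x, training = TRUE, keep_cache = TRUE)
      target <- patch$clean; dim(target) <- dim(y)
      resid <- y - target
      if (!all(is.finite(resid)))
        stopf("non-finite loss at epoch %d; aborting", epoch)
      epoch_loss <- epoch_loss + sum(resid^2)
      n_seen <- n_seen + 1L
      grads <- unet_backward(network, y, 2 * resid)
      batch_grads <- if (is.null(batch_grads)) grads
                     else purrr::map2(batch_grads, grads, `+`)
      batch_count <- batch_count + 1L
      if (batch_count == config$batch_size || ti == order_idx[length(order_idx)]) {
        st <- adam_step(network$params, batch_grads, opt, sched$lr)
        network$params <- st$params
        opt <- st$opt
        batch_grads <- NULL
        batch_count <- 0L
      }
    }
    train_loss <- epoch_loss / n_seen

    val_loss <- mean(vapply(val_patches, function(p) {
      x <- stack_channels(p$noisy, p$ct, in_ch)
      y <- unet_forward(network, x, training = FALSE)
      target <- p$clean; dim(target) <- dim(y)
      sse_loss(y, target)
    }, numeric(1)))

    lr_now <- sched$lr
    sched <- scheduler_step(sched, val_loss)
    if (sched$best_epoch == epoch) best_params <- network$params
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss, lr = lr_now)
    if (verbose)
      message(sprintf("epoch %3d  train %.6g  val %.6g  lr %.3g",
                      epoch, train_loss, val_loss, lr_now))
    if (sched$stop) break
  }
  network$params <- best_params
  structure(list(network = network, history = dplyr::bind_rows(history),
                 best_epoch = sched$best_epoch, best_val_loss = sched$best),
            class = "mc_unet_fit")
}

#' @export
print.mc_unet_fit <- function(x, ...) {
  cat(sprintf("<mc_unet_fit> %d epochs, best epoch %d (val loss %.6g)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Per-epoch training history
#'
#' @param x An `mc_unet_fit`.
#' @param ... Unused.
#' @return Tibble with epoch, train_loss, val_loss, lr.
#' @export
tidy.mc_unet_fit <- function(x, ...) x$history

#' @export
glance.mc_unet_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 final_train_loss = x$history$train_loss[nrow(x$history)],
                 final_lr = x$history$lr[nrow(x$history)])
}

#' Plot a training history
#'
#' @param object An `mc_unet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_unet_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "summed-squared-error loss", colour = NULL)
}
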