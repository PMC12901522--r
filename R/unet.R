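#' Configure the 3D U-net denoiser
#'
#' The denoiser is an encoder-decoder with skip connections at every
#' resolution level. `levels` is the number of down-sampling steps, so there
#' are `levels + 1` resolution levels; each carries two 3x3x3 same-padded
#' convolutions (+ ReLU, optional batch normalization). The first pooling is
#' 3x3x1 voxels (motivated by the coplanar arc setup: no early resolution
#' loss along the rotation axis), deeper poolings are 2x2x2. Upsampling is a
#' learned transposed convolution with kernel equal to the corresponding
#' pooling stride, followed by skip concatenation and two convolutions; a
#' final 1x1x1 convolution maps to one output channel.
#'
#' With the defaults (two input channels, 4 down-sampling steps, width
#' ladder 32-512, no batch normalization, z-size 64) the parameter count is
#' 22,578,241, i.e. 2.2578e7.
#'
#' @param in_channels 1 (dose only) or 2 (dose + CT).
#' @param z_size Input extent along z: one of 32, 64, 96.
#' @param xy_size Input extent along x and y (default 192).
#' @param levels Number of down-sampling steps (default 4, minimum 2).
#' @param channel_widths Widths of the `levels + 1` resolution levels;
#'   default a doubling ladder starting at `base_width`.
#' @param base_width First-level width used when `channel_widths` is NULL
#'   (default 32).
#' @param batch_norm Include batch normalization after every convolution?
#' @param out_channels Output channels (default 1).
#' @return A list of class `mc_unet_config`.
#' @examples
#' count_parameters(unet_config())
#' count_parameters(unet_config(base_width = 4, xy_size = 48, z_size = 16))
#' @export
unet_config <- function(in_channels = 2, z_size = 64, xy_size = 192,
                        levels = 4, channel_widths = NULL, base_width = 32,
                        batch_norm = FALSE, out_channels = 1) {
  if (!in_channels %in% c(1, 2)) stopf("`in_channels` must be 1 or 2")
  if (levels < 2) stopf("`levels` must be at least 2")
  if (is.null(channel_widths)) channel_widths <- base_width * 2^(0:levels)
  if (length(channel_widths) != levels + 1 || any(channel_widths < 1))
    stopf("`channel_widths` must give %d strictly positive widths", levels + 1)
  cfg <- structure(list(in_channels = as.integer(in_channels),
                        z_size = as.integer(z_size),
                        xy_size = as.integer(xy_size),
                        levels = as.integer(levels),
                        channel_widths = as.integer(channel_widths),
                        kernel = c(3L, 3L, 3L),
                        first_pool = c(3L, 3L, 1L),
                        deeper_pool = c(2L, 2L, 2L),
                        batch_norm = isTRUE(batch_norm),
                        out_channels = as.integer(out_channels)),
                   class = "mc_unet_config")
  check_divisibility(cfg)
  cfg
}

pool_strides <- function(config) {
  c(list(config$first_pool),
    rep(list(config$deeper_pool), config$levels - 1L))
}

check_divisibility <- function(config) {
  d <- c(config$xy_size, config$xy_size, config$z_size)
  strides <- pool_strides(config)
  for (l in seq_along(strides)) {
    s <- strides[[l]]
    for (a in 1:3) {
      if (d[a] %% s[a] != 0L)
        stopf("input extent %d along axis %s is not divisible by the pooling at level %d (stride %d)",
              d[a], c("x", "y", "z")[a], l, s[a], class = "mcdose_config_error")
    }
    d <- d %/% s
  }
  invisible(TRUE)
}

#' The five candidate model configurations
#'
#' The candidates differ by z input size (32/64/96), by whether the CT is a
#' second input channel, and by batch normalization. Candidate 2 (z = 64,
#' CT input, no batch normalization) is the selected production model.
#'
#' @return A named list of five [unet_config()]s.
#' @export
unet_candidates <- function() {
  list(model1 = unet_config(in_channels = 2, z_size = 32, batch_norm = FALSE),
       model2 = unet_config(in_channels = 2, z_size = 64, batch_norm = FALSE),
       model3 = unet_config(in_channels = 2, z_size = 96, batch_norm = FALSE),
       model4 = unet_config(in_channels = 1, z_size = 64, batch_norm = FALSE),
       model5 = unet_config(in_channels = 2, z_size = 64, batch_norm = TRUE))
}

#' Layer-by-layer network specification with closed-form parameter counts
#'
#' @param config An [unet_config()].
#' @return A tibble with one row per parameterized layer: `layer`, `kind`,
#'   `c_in`, `c_out`, `kernel`, `params` (weights `+` biases).
#' @export
network_spec <- function(config) {
  stopifnot(inherits(config, "mc_unet_config"))
  w <- config$channel_widths
  L <- config$levels
  strides <- pool_strides(config)
  rows <- list()
  add <- function(layer, kind, c_in, c_out, kernel, params) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      layer = layer, kind = kind, c_in = c_in, c_out = c_out,
      kernel = paste(kernel, collapse = "x"), params = params)
  }
  conv_block <- function(prefix, c_in, c_out) {
    add(paste0(prefix, ".conv1"), "conv3", c_in, c_out, c(3, 3, 3),
        c_in * c_out * 27 + c_out)
    if (config$batch_norm)
      add(paste0(prefix, ".bn1"), "batchnorm", c_out, c_out, 1, 2 * c_out)
    add(paste0(prefix, ".conv2"), "conv3", c_out, c_out, c(3, 3, 3),
        c_out * c_out * 27 + c_out)
    if (config$batch_norm)
      add(paste0(prefix, ".bn2"), "batchnorm", c_out, c_out, 1, 2 * c_out)
  }
  c_prev <- config$in_channels
  for (l in seq_len(L + 1L)) {
    conv_block(paste0("enc", l), c_prev, w[l])
    c_prev <- w[l]
  }
  for (l in rev(seq_len(L))) {
    s <- strides[[l]]
    add(paste0("up", l), "upconv", w[l + 1L], w[l], s,
        w[l + 1L] * w[l] * prod(s) + w[l])
    conv_block(paste0("dec", l), 2L * w[l], w[l])
  }
  add("final", "conv1", w[1], config$out_channels, c(1, 1, 1),
      w[1] * config$out_channels + config$out_channels)
  dplyr::bind_rows(rows)
}

#' Closed-form trainable parameter count
#'
#' Sums the layer descriptors of [network_spec()]; equals the instantiated
#' network's parameter count (sum of the lengths of its weight arrays)
#' exactly.
#'
#' @param config An [unet_config()].
#' @return Integer-valued count.
#' @export
count_parameters <- function(config) {
  sum(network_spec(config)$params)
}

init_weight <- function(shape, fan_in, rng_sd = sqrt(2 / fan_in)) {
  array(rnorm(prod(shape), 0, rng_sd), shape)
}

#' Instantiate a trainable 3D U-net
#'
#' Builds the network of [unet_config()] with He fan-in Gaussian weight
#' initialization (seeded) and zero biases. The forward contract maps an
#' input of shape `(xy, xy, z, in_channels)` to `(xy, xy, z, 1)`.
#'
#' @param config An [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mc_unet`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mc_unet_config"))
  check_divisibility(config)
  set.seed(as.integer(seed))
  w <- config$channel_widths
  L <- config$levels
  strides <- pool_strides(config)
  params <- list()
  state <- list()
  conv_params <- function(name, c_in, c_out) {
    params[[paste0(name, ".W")]] <<- init_weight(c(27L * c_in, c_out), 27 * c_in)
    params[[paste0(name, ".b")]] <<- numeric(c_out)
  }
  bn_params <- function(name, c_out) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c_out)
    params[[paste0(name, ".beta")]] <<- numeric(c_out)
    state[[paste0(name, ".mean")]] <<- numeric(c_out)
    state[[paste0(name, ".var")]] <<- rep(1, c_out)
  }
  block_params <- function(prefix, c_in, c_out) {
    conv_params(paste0(prefix, ".conv1"), c_in, c_out)
    if (config$batch_norm) bn_params(paste0(prefix, ".bn1"), c_out)
    conv_params(paste0(prefix, ".conv2"), c_out, c_out)
    if (config$batch_norm) bn_params(paste0(prefix, ".bn2"), c_out)
  }
  c_prev <- config$in_channels
  for (l in seq_len(L + 1L)) {
    block_params(paste0("enc", l), c_prev, w[l])
    c_prev <- w[l]
  }
  for (l in rev(seq_len(L))) {
    s <- strides[[l]]
    params[[paste0("up", l, ".W")]] <- init_weight(c(w[l + 1L], prod(s) * w[l]), w[l + 1L])
    params[[paste0("up", l, ".b")]] <- numeric(w[l])
    block_params(paste0("dec", l), 2L * w[l], w[l])
  }
  params[["final.W"]] <- init_weight(c(w[1], config$out_channels), w[1])
  params[["final.b"]] <- numeric(config$out_channels)
  structure(list(config = config, params = params, state = state),
            class = "mc_unet")
}

#' @export
print.mc_unet <- function(x, ...) {
  cat(sprintf("<mc_unet> %d levels, widths %s, in=%d, %s; %s parameters\n",
              x$config$levels,
              paste(x$config$channel_widths, collapse = "/"),
              x$config$in_channels,
              if (x$config$batch_norm) "batch norm" else "no batch norm",
              format(network_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Instantiated parameter count (framework introspection)
#'
#' Counts parameters by summing the lengths of the network's weight arrays;
#' the independent cross-check for [count_parameters()].
#'
#' @param network An `mc_unet`.
#' @return Integer-valued count.
#' @export
network_parameters <- function(network) {
  sum(vapply(network$params, length, numeric(1)))
}

#' Summarise a network's layers
#'
#' @param x An `mc_unet`.
#' @param ... Unused.
#' @return The [network_spec()] tibble of its configuration.
#' @export
tidy.mc_unet <- function(x, ...) network_spec(x$config)

#' @export
glance.mc_unet <- function(x, ...) {
  tibble::tibble(levels = x$config$levels,
                 in_channels = x$config$in_channels,
                 z_size = x$config$z_size,
                 batch_norm = x$config$batch_norm,
                 parameters = network_parameters(x))
}

run_block <- function(net, prefix, h, training, cache) {
  p <- net$params
  for (cv in c("conv1", "conv2")) {
    nm <- paste0(prefix, ".", cv)
    x_in <- h
    h <- conv3_forward(h, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]])
    if (!is.null(cache)) cache[[paste0(nm, ".x")]] <- x_in
    if (net$config$batch_norm) {
      bnm <- paste0(prefix, ".", sub("conv", "bn", cv))
      bc <- bn_forward(h, p[[paste0(bnm, ".gamma")]], p[[paste0(bnm, ".beta")]],
                       net$state[[paste0(bnm, ".mean")]],
                       net$state[[paste0(bnm, ".var")]], training)
      h <- bc$y
      if (!is.null(cache)) cache[[paste0(bnm, ".cache")]] <- bc
    }
    h <- relu_forward(h)
    if (!is.null(cache)) cache[[paste0(nm, ".relu")]] <- h
  }
  list(h = h, cache = cache)
}

#' Forward pass of the U-net
#'
#' @param network An `mc_unet`.
#' @param x Input array `(nx, ny, nz, in_channels)`; spatial dims must be
#'   divisible by the cumulative pooling.
#' @param training Use batch statistics in batch-norm layers?
#' @param keep_cache Keep intermediate activations for [unet_backward()]?
#' @return The output array `(nx, ny, nz, out_channels)`, with the cache as
#'   attribute `"cache"` when requested.
#' @export
unet_forward <- function(network, x, training = FALSE, keep_cache = FALSE) {
  cfg <- network$config
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[4] != cfg$in_channels)
    stopf("input has %d channels, config expects %d", d[4], cfg$in_channels)
  strides <- pool_strides(cfg)
  cache <- if (keep_cache) list() else NULL
  L <- cfg$levels
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L + 1L)) {
    rb <- run_block(network, paste0("enc", l), h, training, cache)
    h <- rb$h; cache <- rb$cache
    if (l <= L) {
      skips[[l]] <- h
      mp <- maxpool_forward(h, strides[[l]])
      h <- mp$y
      if (keep_cache) cache[[paste0("pool", l)]] <- mp
    }
  }
  for (l in rev(seq_len(L))) {
    nm <- paste0("up", l)
    x_in <- h
    h <- upconv_forward(h, network$params[[paste0(nm, ".W")]],
                        network$params[[paste0(nm, ".b")]], strides[[l]])
    if (keep_cache) cache[[paste0(nm, ".x")]] <- x_in
    h <- concat_channels(h, skips[[l]])
    rb <- run_block(network, paste0("dec", l), h, training, cache)
    h <- rb$h; cache <- rb$cache
  }
  if (keep_cache) cache[["final.x"]] <- h
  out <- conv1_forward(h, network$params[["final.W"]], network$params[["final.b"]])
  if (keep_cache) attr(out, "cache") <- cache
  out
}

block_backward <- function(net, prefix, cache, dh, grads) {
  p <- net$params
  for (cv in c("conv2", "conv1")) {
    nm <- paste0(prefix, ".", cv)
    dh <- relu_backward(cache[[paste0(nm, ".relu")]], dh)
    if (net$config$batch_norm) {
      bnm <- paste0(prefix, ".", sub("conv", "bn", cv))
      bb <- bn_backward(cache[[paste0(bnm, ".cache")]],
                        p[[paste0(bnm, ".gamma")]], dh)
      dh <- bb$dx
      grads[[paste0(bnm, ".gamma")]] <- bb$dgamma
      grads[[paste0(bnm, ".beta")]] <- bb$dbeta
    }
    cb <- conv3_backward(cache[[paste0(nm, ".x")]], p[[paste0(nm, ".W")]], dh)
    dh <- cb$dx
    grads[[paste0(nm, ".W")]] <- cb$dW
    grads[[paste0(nm, ".b")]] <- cb$db
  }
  list(dh = dh, grads = grads)
}

#' Backward pass of the U-net
#'
#' @param network An `mc_unet`.
#' @param output Output of [unet_forward()] with `keep_cache = TRUE`.
#' @param dout Gradient of the loss with respect to the output.
#' @return A named list of parameter gradients (same names as
#'   `network$params`).
#' @export
unet_backward <- function(network, output, dout) {
  cache <- attr(output, "cache")
  if (is.null(cache)) stopf("forward pass was run without `keep_cache = TRUE`")
  cfg <- network$config
  strides <- pool_strides(cfg)
  L <- cfg$levels
  grads <- list()

  cb <- conv1_backward(cache[["final.x"]], network$params[["final.W"]], dout)
  dh <- cb$dx
  grads[["final.W"]] <- cb$dW
  grads[["final.b"]] <- cb$db

  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    bb <- block_backward(network, paste0("dec", l), cache, dh, grads)
    dh <- bb$dh; grads <- bb$grads
    w_l <- cfg$channel_widths[l]
    dup <- dh[, , , seq_len(w_l), drop = FALSE]
    dskips[[l]] <- dh[, , , w_l + seq_len(w_l), drop = FALSE]
    nm <- paste0("up", l)
    ub <- upconv_backward(cache[[paste0(nm, ".x")]],
                          network$params[[paste0(nm, ".W")]], strides[[l]], dup)
    dh <- ub$dx
    grads[[paste0(nm, ".W")]] <- ub$dW
    grads[[paste0(nm, ".b")]] <- ub$db
  }
  for (l in (L + 1L):1L) {
    if (l <= L) {
      dh <- maxpool_backward(cache[[paste0("pool", l)]], dh)
      dh <- dh + dskips[[l]]
    }
    bb <- block_backward(network, paste0("enc", l), cache, dh, grads)
    dh <- bb$dh; grads <- bb$grads
  }
  grads
}

#' Construct an identity network for chain diagnostics
#'
#' Sets the weights of a (no batch-norm) configuration so the network output
#' equals its first input channel exactly for non-negative inputs: the
#' top-level skip path carries the input through centre-tap convolutions and
#' all other weights are zero. Used to verify that the full
#' scale/pad/patch/aggregate/unscale chain of [denoise_volume()] is exactly
#' invertible.
#'
#' @param config An [unet_config()] with `batch_norm = FALSE`.
#' @return An `mc_unet` computing the identity on channel 1.
#' @export
make_identity_network <- function(config) {
  stopifnot(inherits(config, "mc_unet_config"))
  if (config$batch_norm) stopf("identity construction requires `batch_norm = FALSE`")
  net <- build_network(config, seed = 1L)
  net$params <- lapply(net$params, function(p) { p[] <- 0; p })
  w1 <- config$channel_widths[1]
  centre_tap <- function(c_in, from, to) {
    # row index of the centre tap (di=dj=dk=1) of input channel `from`
    (from - 1L) * 27L + 14L
  }
  # enc1.conv1: feature 1 <- input channel 1 (centre tap)
  net$params[["enc1.conv1.W"]][centre_tap(config$in_channels, 1L), 1L] <- 1
  # enc1.conv2: feature 1 -> feature 1
  net$params[["enc1.conv2.W"]][centre_tap(w1, 1L), 1L] <- 1
  # dec1 sees concat(upsampled, skip): skip's feature 1 is channel w1 + 1
  net$params[["dec1.conv1.W"]][centre_tap(2L * w1, w1 + 1L), 1L] <- 1
  net$params[["dec1.conv2.W"]][centre_tap(w1, 1L), 1L] <- 1
  net$params[["final.W"]][1L, 1L] <- 1
  net
}
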