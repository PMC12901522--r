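# Layer primitives for the 3D U-net: forward and backward passes written
# against plain R arrays, with 3x3x3 convolutions lowered to matrix
# multiplications (im2col + GEMM) so the heavy lifting runs in BLAS.
# Tensors are (nx, ny, nz, channels); weights for a 3x3x3 convolution are a
# (27 * c_in) x c_out matrix with rows ordered tap-x fastest, then tap-y,
# tap-z, then input channel.

conv3_forward <- function(x, W, b) {
  .conv3_fwd(x, dim(x), W, b)
}

conv3_backward <- function(x, W, dy) {
  .conv3_bwd(x, dim(x), W, dy)
}

conv1_forward <- function(x, W, b) {
  d <- dim(x)
  m <- x; dim(m) <- c(prod(d[1:3]), d[4])
  y <- sweep(m %*% W, 2, b, `+`)
  dim(y) <- c(d[1:3], length(b))
  y
}

conv1_backward <- function(x, W, dy) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  m <- x; dim(m) <- c(nvox, d[4])
  dym <- dy; dim(dym) <- c(nvox, dim(dy)[4])
  dx <- tcrossprod(dym, W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(m, dym), db = colSums(dym))
}

relu_forward <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(y, dy) {
  # y is the forward output; gradient passes where y > 0
  dy * (y > 0)
}

# max-pooling along one axis (axis permuted to the front), stride s
pool_axis <- function(x, axis, s) {
  nd <- length(dim(x))
  perm <- c(axis, setdiff(seq_len(nd), axis))
  xa <- aperm(x, perm)
  da <- dim(xa)
  if (da[1] %% s != 0L)
    stopf("axis %d extent %d not divisible by pool stride %d", axis, da[1], s)
  m <- matrix(xa, nrow = s)
  best <- m[1, ]
  arg <- rep.int(1L, ncol(m))
  if (s > 1) for (a in 2:s) {
    sel <- m[a, ] > best
    best[sel] <- m[a, sel]
    arg[sel] <- a
  }
  y <- array(best, c(da[1] %/% s, da[-1]))
  list(y = aperm(y, order(perm)), arg = arg, perm = perm, da = da, s = s)
}

pool_axis_backward <- function(cache, dy) {
  dya <- aperm(dy, cache$perm)
  dm <- matrix(0, nrow = cache$s, ncol = length(dya))
  dm[cbind(cache$arg, seq_along(dya))] <- as.numeric(dya)
  dxa <- array(dm, cache$da)
  aperm(dxa, order(cache$perm))
}

maxpool_forward <- function(x, stride) {
  caches <- list()
  for (axis in 1:3) {
    if (stride[axis] > 1L) {
      pc <- pool_axis(x, axis, stride[axis])
      x <- pc$y
      caches[[length(caches) + 1L]] <- pc
    }
  }
  list(y = x, caches = caches)
}

maxpool_backward <- function(cache, dy) {
  for (pc in rev(cache$caches)) dy <- pool_axis_backward(pc, dy)
  dy
}

# transposed convolution with kernel == stride (learned upsampling): every
# input voxel expands into an (sx, sy, sz) output block, so the operation is
# a single GEMM plus a deterministic reshuffle (no overlapping taps).
# W is (c_in) x (S * c_out) with block-offset fastest (x fastest) then c_out.
upconv_forward <- function(x, W, b, stride) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  c_out <- length(b)
  S <- prod(stride)
  m <- x; dim(m) <- c(nvox, d[4])
  ym <- m %*% W
  A <- array(ym, c(d[1:3], stride, c_out))
  out <- aperm(A, c(4L, 1L, 5L, 2L, 6L, 3L, 7L))
  dim(out) <- c(d[1] * stride[1], d[2] * stride[2], d[3] * stride[3], c_out)
  sweep(out, 4, b, `+`)
}

upconv_backward <- function(x, W, stride, dy) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  c_out <- dim(dy)[4]
  dA <- dy
  dim(dA) <- c(stride[1], d[1], stride[2], d[2], stride[3], d[3], c_out)
  dA <- aperm(dA, c(2L, 4L, 6L, 1L, 3L, 5L, 7L))
  dym <- dA; dim(dym) <- c(nvox, prod(stride) * c_out)
  m <- x; dim(m) <- c(nvox, d[4])
  dxm <- tcrossprod(dym, W)
  dim(dxm) <- d
  dyc <- dy; dim(dyc) <- c(length(dy) %/% c_out, c_out)
  list(dx = dxm, dW = crossprod(m, dym), db = colSums(dyc))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[1:3], db[1:3]))
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# batch normalization over the spatial dims of one sample (training mode)
# or with running statistics (evaluation mode)
bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       eps = 1e-5) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  m <- x; dim(m) <- c(nvox, d[4])
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(sweep(m, 2, mu)^2)
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- d
  list(y = y, xhat = xhat, inv_sd = inv_sd, mu = mu, v = v)
}

bn_backward <- function(cache, gamma, dy) {
  d <- dim(dy)
  nvox <- prod(d[1:3])
  dym <- dy; dim(dym) <- c(nvox, d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, `*`)
  # standard batch-norm gradient with batch statistics
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$inv_sd, `*`)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}
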