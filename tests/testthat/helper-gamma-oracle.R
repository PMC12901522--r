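# Independent exhaustive gamma oracle: for every reference voxel above the
# threshold, every offset of the fine search grid is evaluated directly from
# the gamma definition (no ordering, no early termination). Shares no code
# with the package's optimized search.
#
# Because the offset grid is the same for every voxel, the trilinear
# interpolation weights are constant across voxels; only the base index and
# the in-bounds mask change. The evaluated volume is zero-padded by one
# layer on the high side so offsets landing exactly on the last voxel plane
# (fractional part 0) index real memory with weight zero.

gamma_oracle <- function(reference, evaluated, criteria) {
  ref <- reference$values
  d <- dim(ref)
  vox_mm <- reference$voxel_size * 10
  dmax <- max(ref)
  dD <- criteria$dose_percent / 100 * dmax
  thresh <- criteria$low_dose_threshold / 100 * dmax
  step <- criteria$interpolation_step_mm
  nst <- floor(criteria$search_radius_mm / step)
  offs <- as.matrix(expand.grid(x = (-nst:nst) * step, y = (-nst:nst) * step,
                                z = (-nst:nst) * step))
  keep <- rowSums(offs^2) <= criteria$search_radius_mm^2
  offs <- offs[keep, , drop = FALSE]
  dist_term <- rowSums(offs^2) / criteria$distance_mm^2

  ox <- offs[, 1] / vox_mm[1]; oy <- offs[, 2] / vox_mm[2]; oz <- offs[, 3] / vox_mm[3]
  flx <- floor(ox); fly <- floor(oy); flz <- floor(oz)
  fx <- ox - flx; fy <- oy - fly; fz <- oz - flz

  dp <- d + 1L
  evp <- array(0, dp)
  evp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- evaluated$values
  sx <- 1; sy <- dp[1]; sz <- dp[1] * dp[2]
  lin_off <- flx * sx + fly * sy + flz * sz

  w000 <- (1 - fx) * (1 - fy) * (1 - fz); w100 <- fx * (1 - fy) * (1 - fz)
  w010 <- (1 - fx) * fy * (1 - fz); w110 <- fx * fy * (1 - fz)
  w001 <- (1 - fx) * (1 - fy) * fz; w101 <- fx * (1 - fy) * fz
  w011 <- (1 - fx) * fy * fz; w111 <- fx * fy * fz

  # per-axis in-bounds masks depend only on the voxel index along that axis
  okx <- lapply(seq_len(d[1]), function(i) ox >= -(i - 1) & ox <= d[1] - i)
  oky <- lapply(seq_len(d[2]), function(j) oy >= -(j - 1) & oy <= d[2] - j)
  okz <- lapply(seq_len(d[3]), function(k) oz >= -(k - 1) & oz <= d[3] - k)

  all_x <- vapply(okx, all, logical(1))
  all_y <- vapply(oky, all, logical(1))
  all_z <- vapply(okz, all, logical(1))

  g <- array(NA_real_, d)
  idx <- which(ref >= thresh, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    anchor <- 1 + (i - 1) * sx + (j - 1) * sy + (k - 1) * sz
    if (all_x[i] && all_y[j] && all_z[k]) {
      base <- anchor + lin_off
      val <- w000 * evp[base] + w100 * evp[base + sx] +
        w010 * evp[base + sy] + w110 * evp[base + sy + sx] +
        w001 * evp[base + sz] + w101 * evp[base + sz + sx] +
        w011 * evp[base + sz + sy] + w111 * evp[base + sz + sy + sx]
      g2 <- dist_term + ((val - ref[i, j, k]) / dD)^2
    } else {
      ok <- okx[[i]] & oky[[j]] & okz[[k]]
      base <- anchor + lin_off[ok]
      val <- w000[ok] * evp[base] + w100[ok] * evp[base + sx] +
        w010[ok] * evp[base + sy] + w110[ok] * evp[base + sy + sx] +
        w001[ok] * evp[base + sz] + w101[ok] * evp[base + sz + sx] +
        w011[ok] * evp[base + sz + sy] + w111[ok] * evp[base + sz + sy + sx]
      g2 <- dist_term[ok] + ((val - ref[i, j, k]) / dD)^2
    }
    g[i, j, k] <- sqrt(min(g2))
  }
  pass <- g[!is.na(g)] <= 1 + 1e-9
  list(gamma = g, pass_rate = 100 * mean(pass))
}
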