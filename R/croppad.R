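#' Centrally crop or zero-pad a volume in x and y
#'
#' Brings the xy footprint of a volume to the network input size. Axes larger
#' than `xy_size` are cropped centrally (on an odd surplus the extra voxel is
#' removed from the high-index side, i.e. the retained window is left-biased);
#' axes smaller than `xy_size` are zero-padded symmetrically (on an odd
#' deficit the extra pad voxel goes to the high-index side). The z axis is
#' untouched. The returned placement record allows exact restoration of a
#' result into the original frame with [restore_xy()].
#'
#' @param volume An [mc_volume()] (or plain 3D array).
#' @param xy_size Target number of voxels in x and y (default 192).
#' @return A list with elements `volume` (the resized [mc_volume()]) and
#'   `placement` (a record of per-axis source/target windows).
#' @examples
#' v <- mc_volume(array(stats::runif(20 * 20 * 4), c(20, 20, 4)))
#' out <- crop_or_pad_xy(v, xy_size = 16)
#' dim(out$volume$values)
#' @export
crop_or_pad_xy <- function(volume, xy_size = 192) {
  check_number(xy_size, "xy_size", lower = 1, allow_zero = TRUE)
  xy_size <- as.integer(xy_size)
  is_vol <- inherits(volume, "mc_volume")
  vals <- as_volume_values(volume)
  d <- dim(vals)

  win <- function(n, target) {
    if (n >= target) {
      # central crop, left-biased: start = floor((n - target)/2) (0-based)
      start <- (n - target) %/% 2L
      list(src = c(start + 1L, start + target), dst = c(1L, target))
    } else {
      pad <- (target - n) %/% 2L
      list(src = c(1L, n), dst = c(pad + 1L, pad + n))
    }
  }
  wx <- win(d[1], xy_size)
  wy <- win(d[2], xy_size)

  out <- array(0, c(xy_size, xy_size, d[3]))
  out[wx$dst[1]:wx$dst[2], wy$dst[1]:wy$dst[2], ] <-
    vals[wx$src[1]:wx$src[2], wy$src[1]:wy$src[2], , drop = FALSE]

  placement <- list(original_dim = d, xy_size = xy_size, x = wx, y = wy)
  if (is_vol) {
    # origin moves with the retained window (crop) or pad offset
    shift <- c((wx$src[1] - wx$dst[1]) * volume$voxel_size[1],
               (wy$src[1] - wy$dst[1]) * volume$voxel_size[2], 0)
    out <- mc_volume(out, voxel_size = volume$voxel_size, origin = volume$origin + shift)
  }
  list(volume = out, placement = placement)
}

#' Restore a cropped/padded volume into its original frame
#'
#' Exact inverse placement for [crop_or_pad_xy()]: voxels that were cropped
#' away are filled with `fill` (default 0); padded voxels are discarded.
#'
#' @param volume The resized volume (output frame of [crop_or_pad_xy()]).
#' @param placement Placement record from [crop_or_pad_xy()].
#' @param fill Value for voxels outside the retained window.
#' @return A 3D array (or [mc_volume()] if `volume` is one) with the
#'   original dimensions.
#' @export
restore_xy <- function(volume, placement, fill = 0) {
  is_vol <- inherits(volume, "mc_volume")
  vals <- as_volume_values(volume)
  d <- placement$original_dim
  stopifnot(identical(dim(vals)[1:2], c(placement$xy_size, placement$xy_size)))
  out <- array(fill, c(d[1], d[2], dim(vals)[3]))
  wx <- placement$x; wy <- placement$y
  out[wx$src[1]:wx$src[2], wy$src[1]:wy$src[2], ] <-
    vals[wx$dst[1]:wx$dst[2], wy$dst[1]:wy$dst[2], , drop = FALSE]
  if (is_vol) out <- mc_volume(out, voxel_size = volume$voxel_size,
                               origin = volume$origin -
                                 c((wx$src[1] - wx$dst[1]) * volume$voxel_size[1],
                                   (wy$src[1] - wy$dst[1]) * volume$voxel_size[2], 0))
  out
}
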