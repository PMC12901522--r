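#' Plan the z-patch layout for full-volume inference
#'
#' Volumes taller than the network's z input are processed in overlapping
#' z-patches. The layout uses the minimal number of patches
#' `ceiling(z_extent / patch_z)`, the first at corner 0 and the last at
#' `z_extent - patch_z`, with the remaining corners spaced as evenly as
#' possible (equalized overlaps). Volumes with `z_extent <= patch_z` get a
#' single patch and are zero-padded up to `patch_z`.
#'
#' @param z_extent Volume extent along z (voxels).
#' @param patch_z Network input extent along z.
#' @return A list of class `mc_patch_layout`: `corners` (0-based), `patch_z`,
#'   `z_extent`, `pad_z` (zero-padding applied when the volume is shorter).
#' @examples
#' plan_patches(100, 64)$corners
#' @export
plan_patches <- function(z_extent, patch_z) {
  check_number(z_extent, "z_extent", lower = 1)
  check_number(patch_z, "patch_z", lower = 1)
  if (z_extent <= patch_z) {
    corners <- 0L
    pad_z <- as.integer(patch_z - z_extent)
  } else {
    n <- ceiling(z_extent / patch_z)
    corners <- as.integer(round(seq(0, z_extent - patch_z, length.out = n)))
    pad_z <- 0L
  }
  structure(list(corners = corners, patch_z = as.integer(patch_z),
                 z_extent = as.integer(z_extent), pad_z = pad_z),
            class = "mc_patch_layout")
}

#' Denoise a full dose volume
#'
#' The complete inference chain: scale both channels by the dataset
#' constants (power-of-two variants, so scaling is exactly invertible),
#' centrally crop or zero-pad xy to the network footprint, run the network
#' over the z-patch layout of [plan_patches()], average overlapping voxels
#' (unweighted mean), restore the original frame through the placement
#' record, unscale, clip negative predictions to zero and zero everything
#' outside the body mask.
#'
#' @param network A trained `mc_unet`.
#' @param noisy High-noise dose [mc_volume()] (Gy/MU).
#' @param ct CT [mc_volume()] (HU) on the same grid.
#' @param scales [compute_scale_constants()] output.
#' @param body_mask Logical 3D array on the same grid.
#' @return Denoised dose [mc_volume()].
#' @export
denoise_volume <- function(network, noisy, ct, scales, body_mask) {
  stopifnot(inherits(network, "mc_unet"), inherits(scales, "mc_scale_constants"))
  if (!same_grid(noisy, ct)) stopf("noisy and ct geometry mismatch")
  cfg <- network$config
  d <- dim(noisy$values)
  if (!identical(dim(body_mask), d)) stopf("body mask geometry mismatch")

  dose_s <- scale_dose(noisy$values, scales)
  ct_s <- scale_ct(ct$values, scales)

  cp_d <- crop_or_pad_xy(mc_volume(dose_s, noisy$voxel_size, noisy$origin), cfg$xy_size)
  cp_c <- crop_or_pad_xy(mc_volume(ct_s, ct$voxel_size, ct$origin), cfg$xy_size)
  dv <- cp_d$volume$values
  cv <- cp_c$volume$values

  layout <- plan_patches(d[3], cfg$z_size)
  if (layout$pad_z > 0L) {
    padz <- function(v) {
      out <- array(0, c(dim(v)[1:2], layout$patch_z))
      out[, , seq_len(dim(v)[3])] <- v
      out
    }
    dv <- padz(dv); cv <- padz(cv)
  }

  acc <- array(0, dim(dv))
  cnt <- array(0, dim(dv))
  for (corner in layout$corners) {
    zs <- corner + seq_len(layout$patch_z)
    x <- stack_channels(dv[, , zs, drop = FALSE], cv[, , zs, drop = FALSE],
                        cfg$in_channels)
    y <- unet_forward(network, x, training = FALSE)
    dim(y) <- dim(y)[1:3]
    acc[, , zs] <- acc[, , zs] + y
    cnt[, , zs] <- cnt[, , zs] + 1
  }
  out <- acc / cnt
  if (layout$pad_z > 0L) out <- out[, , seq_len(d[3]), drop = FALSE]

  restored <- restore_xy(out, cp_d$placement, fill = 0)
  restored <- unscale_dose(restored, scales)
  restored[restored < 0] <- 0
  restored[!body_mask] <- 0
  mc_volume(restored, voxel_size = noisy$voxel_size, origin = noisy$origin)
}

#' Denoise a whole treatment plan
#'
#' Per-field noisy dose grids are summed into one plan dose, which is then
#' denoised in a single pass (matching the workflow: one fast noisy dose
#' per field, one denoising of the whole-plan distribution).
#'
#' @param network A trained `mc_unet`.
#' @param field_doses Non-empty list of [mc_volume()]s on the CT grid.
#' @param ct CT [mc_volume()].
#' @param scales [compute_scale_constants()] output.
#' @param body_mask Logical 3D array.
#' @return Denoised plan dose [mc_volume()].
#' @export
denoise_plan <- function(network, field_doses, ct, scales, body_mask) {
  if (length(field_doses) < 1L) stopf("empty field list")
  for (f in field_doses) if (!same_grid(f, ct)) stopf("field dose not on the CT grid")
  total <- Reduce(`+`, lapply(field_doses, function(f) f$values))
  denoise_volume(network,
                 mc_volume(total, ct$voxel_size, ct$origin),
                 ct, scales, body_mask)
}
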