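#' Dataset-level scale constants for network input/output
#'
#' Both network channels are scaled by one constant factor each so their
#' values land approximately in \[0, 1\]. Per calibration case the
#' normalization factor is the maximum absolute value of the volume, with CT
#' volumes first shifted by +1000 HU so air maps to zero and a single
#' positive factor suffices. The returned constant is the arithmetic mean of
#' the per-case factors and is then fixed for all subsequent data.
#'
#' For applying the scaling inside the network input/output chain, the
#' constants are accompanied by their power-of-two ceilings
#' (`ct_scale_pow2`, `dose_scale_pow2`): dividing and re-multiplying by a
#' power of two is exact in floating point, which makes the whole
#' preprocessing chain exactly invertible (see [denoise_volume()]). The
#' power-of-two constant is within a factor 2 of the calibrated one, so the
#' scaled range remains approximately \[0, 1\].
#'
#' @param calibration_cases A list of cases, each a list with elements `ct`
#'   and `dose` ([mc_volume()]s or arrays; CT in HU, dose in Gy/MU).
#' @return An object of class `mc_scale_constants` with fields `ct_scale`,
#'   `dose_scale`, `ct_scale_pow2`, `dose_scale_pow2`, `hu_shift` (1000).
#' @export
compute_scale_constants <- function(calibration_cases) {
  if (!is.list(calibration_cases) || length(calibration_cases) < 1L)
    stopf("need at least one calibration case")
  ct_max <- vapply(calibration_cases, function(cs)
    max(abs(as_volume_values(cs$ct) + 1000)), numeric(1))
  dose_max <- vapply(calibration_cases, function(cs)
    max(abs(as_volume_values(cs$dose))), numeric(1))
  if (any(ct_max == 0) || any(dose_max == 0))
    stopf("all-zero calibration volume: scale constant would be degenerate")
  ct_scale <- mean(ct_max)
  dose_scale <- mean(dose_max)
  structure(list(ct_scale = ct_scale, dose_scale = dose_scale,
                 ct_scale_pow2 = pow2_ceiling(ct_scale),
                 dose_scale_pow2 = pow2_ceiling(dose_scale),
                 hu_shift = 1000),
            class = "mc_scale_constants")
}

#' @export
print.mc_scale_constants <- function(x, ...) {
  cat(sprintf("<mc_scale_constants> ct: %.6g (pow2 %.6g), dose: %.6g (pow2 %.6g)\n",
              x$ct_scale, x$ct_scale_pow2, x$dose_scale, x$dose_scale_pow2))
  invisible(x)
}

# channel scaling used by training and inference (power-of-two constants,
# so unscale_dose(scale_dose(x)) == x bit-wise)
scale_ct <- function(hu, scales) (hu + scales$hu_shift) / scales$ct_scale_pow2
scale_dose <- function(dose, scales) dose / scales$dose_scale_pow2
unscale_dose <- function(scaled, scales) scaled * scales$dose_scale_pow2
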