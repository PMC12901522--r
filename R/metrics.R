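#' Masked root-mean-squared error
#'
#' RMSE between two dose grids over the voxels whose reference dose exceeds
#' a fraction of the maximum reference dose (default 10%, the convention
#' for reporting dose-grid agreement). Set `threshold_fraction = 0` for the
#' all-voxel variant.
#'
#' @param reference,evaluated [mc_volume()]s on a common grid.
#' @param threshold_fraction Fraction of max reference dose (default 0.10).
#' @return RMSE in the dose unit of the inputs (Gy/MU for engine output).
#' @export
rmse_masked <- function(reference, evaluated, threshold_fraction = 0.10) {
  if (!same_grid(reference, evaluated)) stopf("grid mismatch")
  rv <- reference$values
  dmax <- max(rv)
  if (dmax <= 0) stopf("reference distribution is all zero")
  mask <- rv > threshold_fraction * dmax
  if (!any(mask)) stopf("no voxel above the %g%% threshold", 100 * threshold_fraction)
  sqrt(mean((evaluated$values[mask] - rv[mask])^2))
}

#' Translate a per-MU RMSE to a whole-treatment RMSE
#'
#' Scales a per-monitor-unit dose error to the full treatment course:
#' `rmse_per_mu * mu_per_fraction * (prescription / fraction_dose)`, the
#' number of fractions being prescription over fraction dose.
#'
#' @param rmse_per_mu RMSE in Gy/MU.
#' @param mu_per_fraction Monitor units delivered per fraction.
#' @param prescription Total prescribed dose, Gy.
#' @param fraction_dose Dose per fraction, Gy (> 0).
#' @return Whole-treatment RMSE in Gy.
#' @examples
#' whole_treatment_rmse(1.19e-4, 300, 50, 2) # ~0.9 Gy
#' @export
whole_treatment_rmse <- function(rmse_per_mu, mu_per_fraction, prescription,
                                 fraction_dose) {
  check_number(rmse_per_mu, "rmse_per_mu", lower = 0)
  check_number(mu_per_fraction, "mu_per_fraction", lower = 0, allow_zero = FALSE)
  check_number(prescription, "prescription", lower = 0, allow_zero = FALSE)
  check_number(fraction_dose, "fraction_dose", lower = 0, allow_zero = FALSE)
  rmse_per_mu * mu_per_fraction * (prescription / fraction_dose)
}

#' Improved signal-to-noise ratio
#'
#' Decibel ratio of the noisy input's mean-squared error to the denoised
#' output's mean-squared error against the low-noise reference:
#' `10 * log10(MSE(noisy, reference) / MSE(denoised, reference))` over the
#' masked voxels. Positive values mean denoising moved the distribution
#' closer to the reference.
#'
#' @param noisy,denoised,reference [mc_volume()]s on a common grid.
#' @param mask Logical array of voxels to include (default: all).
#' @return ISNR in dB.
#' @export
isnr <- function(noisy, denoised, reference, mask = NULL) {
  if (!same_grid(noisy, reference) || !same_grid(denoised, reference))
    stopf("grid mismatch")
  if (is.null(mask)) mask <- array(TRUE, dim(reference$values))
  mse_noisy <- mean((noisy$values[mask] - reference$values[mask])^2)
  mse_den <- mean((denoised$values[mask] - reference$values[mask])^2)
  if (mse_den == 0)
    stopf("denoised distribution matches the reference exactly: ISNR is unbounded",
          class = "mcdose_unbounded_isnr")
  10 * log10(mse_noisy / mse_den)
}
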