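#' Monte Carlo noise model for dose grids
#'
#' Multiplicative unit-mean Gamma noise emulating the statistical structure
#' of Monte Carlo dose estimates: per voxel the relative variance scales
#' inversely with the expected number of particle interactions, taken
#' proportional to `histories * clean(v) / max(clean)`. The calibration
#' constant `k0` fixes the Gamma shape at the maximum-dose voxel as
#' `k0 * histories`. The default is calibrated so that the default
#' high-noise setting (`su_reference_histories` = 1.5e6) yields a
#' statistical uncertainty (SU) of about 60% at the reference voxels, and a
#' 200x larger history count (the high/low pairing ratio) stays below 5%.
#'
#' @param k0 Calibration constant (> 0): Gamma shape per history at the
#'   maximum-dose voxel. Default `1 / (0.6^2 * 1.5e6)`.
#' @param su_reference_histories History count at which the target high-SU
#'   level is met (default 1.5e6).
#' @return A list of class `mc_noise_model`.
#' @export
noise_model <- function(k0 = 1 / (0.6^2 * 1.5e6), su_reference_histories = 1.5e6) {
  check_number(k0, "k0", lower = 0, allow_zero = FALSE)
  check_number(su_reference_histories, "su_reference_histories", lower = 0,
               allow_zero = FALSE)
  structure(list(k0 = k0, su_reference_histories = su_reference_histories),
            class = "mc_noise_model")
}

#' Draw a noisy realization of a clean dose grid
#'
#' Per voxel with positive clean dose, `noisy(v) = clean(v) * g_v` with
#' `g_v ~ Gamma(shape = k_v, scale = 1/k_v)` (unit mean), where
#' `k_v = k0 * histories * clean(v) / max(clean)`. Zero-dose voxels stay
#' exactly zero; the result is non-negative everywhere and reproducible
#' given `seed`. Relative noise per voxel scales as `1/sqrt(histories)`.
#'
#' @param clean An [mc_volume()] (or 3D array) of non-negative dose.
#' @param histories Particle-history count (> 0).
#' @param model An [noise_model()].
#' @param seed Integer seed.
#' @return Same container type as `clean`.
#' @export
sample_noisy_dose <- function(clean, histories, model = noise_model(), seed = 1L) {
  check_number(histories, "histories", lower = 0, allow_zero = FALSE)
  stopifnot(inherits(model, "mc_noise_model"))
  vals <- as_volume_values(clean)
  if (!all(is.finite(vals))) stopf("`clean` contains non-finite values")
  if (any(vals < 0)) stopf("`clean` must be non-negative")
  dmax <- max(vals)
  out <- vals
  if (dmax > 0) {
    pos <- which(vals > 0)
    k <- model$k0 * histories * vals[pos] / dmax
    set.seed(as.integer(seed))
    out[pos] <- vals[pos] * rgamma(length(pos), shape = k, scale = 1 / k)
  }
  if (inherits(clean, "mc_volume"))
    mc_volume(out, voxel_size = clean$voxel_size, origin = clean$origin)
  else out
}

#' Estimate the statistical uncertainty of a set of dose realizations
#'
#' SU is the mean, over voxels whose mean dose exceeds 50% of the maximum
#' mean dose, of the per-voxel relative standard error of the mean dose,
#' expressed in percent. This is the conventional reporting statistic for
#' Monte Carlo dose grids; it is invariant under global dose rescaling and
#' decreases as `1/sqrt(B)` with the number of averaged realizations `B`.
#'
#' @param realizations A list of at least two [mc_volume()]s (or arrays) on
#'   a common grid.
#' @return SU in percent.
#' @export
estimate_su <- function(realizations) {
  if (!is.list(realizations) || length(realizations) < 2L)
    stopf("need at least two realizations")
  arrs <- lapply(realizations, as_volume_values)
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1))))
    stopf("realizations must share a common grid")
  B <- length(arrs)
  flat <- vapply(arrs, as.numeric, numeric(prod(d)))
  mu <- rowMeans(flat)
  counted <- mu > 0.5 * max(mu)
  if (!any(counted)) stopf("no voxel above 50% of the maximum mean dose")
  sdv <- apply(flat[counted, , drop = FALSE], 1, sd)
  100 * mean(sdv / sqrt(B) / mu[counted])
}

#' Analytic SU of a single noisy realization under the noise model
#'
#' The per-voxel relative standard deviation implied by the Gamma shape,
#' averaged over voxels above 50% of the maximum clean dose. Useful for
#' labelling dataset noise levels without sampling.
#'
#' @param model An [noise_model()].
#' @param clean Clean dose volume or array.
#' @param histories Particle-history count.
#' @return SU in percent.
#' @export
nominal_su <- function(model, clean, histories) {
  vals <- as_volume_values(clean)
  dmax <- max(vals)
  stopifnot(dmax > 0)
  counted <- vals > 0.5 * dmax
  k <- model$k0 * histories * vals[counted] / dmax
  100 * mean(1 / sqrt(k))
}
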