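BEAM_ENERGIES <- c(6, 10, 15) # nominal MV labels
# per-energy attenuation coefficient (cm^2/g) and penumbra sigma (cm):
# plausible monotone trends (higher energy -> more penetrating, broader penumbra)
MU_ATTEN <- c(`6` = 0.050, `10` = 0.045, `15` = 0.040)
PENUMBRA_SIGMA <- c(`6` = 0.4, `10` = 0.5, `15` = 0.6)

#' Construct one VMAT control point
#'
#' @param gantry_angle Gantry angle in degrees (rotation about the z axis).
#' @param mu_weight Monitor-unit weight, >= 0.
#' @param aperture_halfwidth_x,aperture_halfwidth_y Rectangular aperture
#'   half-widths at the isocenter plane, cm (> 0). The aperture abstracts
#'   the multi-leaf collimator opening.
#' @param collimator_rotation Collimator rotation in degrees.
#' @param energy Beam energy label, one of 6, 10, 15 (MV).
#' @return A list of class `mc_control_point`.
#' @export
control_point <- function(gantry_angle, mu_weight, aperture_halfwidth_x,
                          aperture_halfwidth_y, collimator_rotation = 0,
                          energy = 6) {
  check_number(mu_weight, "mu_weight", lower = 0)
  check_number(aperture_halfwidth_x, "aperture_halfwidth_x", lower = 0, allow_zero = FALSE)
  check_number(aperture_halfwidth_y, "aperture_halfwidth_y", lower = 0, allow_zero = FALSE)
  if (!energy %in% BEAM_ENERGIES)
    stopf("`energy` must be one of %s MV", paste(BEAM_ENERGIES, collapse = ", "))
  structure(list(gantry_angle = gantry_angle, mu_weight = mu_weight,
                 aperture_halfwidth_x = aperture_halfwidth_x,
                 aperture_halfwidth_y = aperture_halfwidth_y,
                 collimator_rotation = collimator_rotation,
                 energy = energy),
            class = "mc_control_point")
}

#' Construct an isocentric VMAT-like arc plan
#'
#' @param control_points List of [control_point()]s (at least one).
#' @param isocenter Length-3 numeric, isocenter position in cm.
#' @param sad Source-axis distance in cm (default 100).
#' @return A list of class `mc_arc_plan` with `total_mu` = sum of control
#'   point MU weights (> 0 required).
#' @export
arc_plan <- function(control_points, isocenter, sad = 100) {
  if (length(control_points) < 1L)
    stopf("an arc needs at least one control point")
  stopifnot(all(vapply(control_points, inherits, logical(1), "mc_control_point")))
  total_mu <- sum(vapply(control_points, `[[`, numeric(1), "mu_weight"))
  if (total_mu <= 0) stopf("total MU must be positive")
  structure(list(control_points = control_points,
                 isocenter = as.numeric(isocenter),
                 sad = sad, total_mu = total_mu),
            class = "mc_arc_plan")
}

#' @export
print.mc_arc_plan <- function(x, ...) {
  cat(sprintf("<mc_arc_plan> %d control points, total %.3g MU, isocenter (%.3g, %.3g, %.3g) cm\n",
              length(x$control_points), x$total_mu,
              x$isocenter[1], x$isocenter[2], x$isocenter[3]))
  invisible(x)
}

#' Summarise an arc plan as a tibble
#'
#' @param x An `mc_arc_plan`.
#' @param ... Unused.
#' @return One row per control point.
#' @export
tidy.mc_arc_plan <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$control_points), function(i) {
    cp <- x$control_points[[i]]
    tibble::tibble(control_point = i, gantry_angle = cp$gantry_angle,
                   mu_weight = cp$mu_weight,
                   aperture_halfwidth_x = cp$aperture_halfwidth_x,
                   aperture_halfwidth_y = cp$aperture_halfwidth_y,
                   collimator_rotation = cp$collimator_rotation,
                   energy = cp$energy)
  }))
}

#' Generate a random clinically-shaped arc plan for a phantom
#'
#' Stand-in for clinically optimized VMAT arcs: control points spread evenly
#' over a full gantry rotation with randomized MU weights and randomized (but
#' per-arc fixed) rectangular aperture half-widths. The isocenter is placed
#' at the phantom body centroid.
#'
#' @param phantom An `mc_phantom`.
#' @param n_control_points Number of control points (default 8).
#' @param seed Integer seed.
#' @param energy Beam energy label (default 6 MV).
#' @return An `mc_arc_plan`.
#' @export
random_arc_plan <- function(phantom, n_control_points = 8, seed = 1L, energy = 6) {
  set.seed(as.integer(seed))
  idx <- which(phantom$body_mask, arr.ind = TRUE)
  iso <- phantom$origin + (colMeans(idx) - 1) * phantom$voxel_size
  hw_x <- runif(1, 1.0, 3.0)
  hw_y <- runif(1, 1.0, 3.0)
  angles <- seq(0, 360, length.out = n_control_points + 1)[-(n_control_points + 1)]
  cps <- lapply(seq_len(n_control_points), function(i) {
    control_point(gantry_angle = angles[i] + runif(1, -2, 2),
                  mu_weight = runif(1, 0.5, 1.5),
                  aperture_halfwidth_x = hw_x,
                  aperture_halfwidth_y = hw_y,
                  collimator_rotation = 0,
                  energy = energy)
  })
  arc_plan(cps, isocenter = iso)
}
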