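#' Gamma analysis criteria
#'
#' Global gamma criteria: the dose criterion is a percentage of the maximum
#' of the reference distribution, the distance-to-agreement criterion is in
#' mm, and voxels below the low-dose threshold (percent of the reference
#' maximum) are excluded from both the gamma map and the pass rate. The
#' search is reference-point-centred over the evaluated distribution, with
#' default search radius 3x the distance criterion and trilinear
#' interpolation at steps of one tenth of the distance criterion.
#'
#' @param dose_percent Dose-difference criterion, % of max reference dose.
#' @param distance_mm Distance-to-agreement criterion, mm.
#' @param low_dose_threshold Low-dose threshold, % of max reference (default 10).
#' @param search_radius_mm Search radius, mm (default `3 * distance_mm`).
#' @param interpolation_step_mm Search-grid step, mm (default `distance_mm / 10`).
#' @param max_gamma Optional search cap: gamma values above it are reported
#'   as the best value found within `max_gamma * distance_mm` of the voxel
#'   (a value `> max_gamma` means "fails by at least this much"). Capping
#'   cannot change pass/fail classification for any cap `> 1`; it bounds
#'   the search cost on badly disagreeing pairs. Default `Inf` (exact map).
#' @return A list of class `mc_gamma_criteria`.
#' @export
gamma_criteria <- function(dose_percent, distance_mm, low_dose_threshold = 10,
                           search_radius_mm = 3 * distance_mm,
                           interpolation_step_mm = distance_mm / 10,
                           max_gamma = Inf) {
  for (nm in c("dose_percent", "distance_mm", "low_dose_threshold",
               "search_radius_mm", "interpolation_step_mm"))
    check_number(get(nm), nm, lower = 0, allow_zero = FALSE)
  if (search_radius_mm < distance_mm)
    stopf("`search_radius_mm` must be at least the distance criterion")
  if (max_gamma <= 1) stopf("`max_gamma` must exceed 1")
  structure(list(dose_percent = dose_percent, distance_mm = distance_mm,
                 low_dose_threshold = low_dose_threshold,
                 search_radius_mm = search_radius_mm,
                 interpolation_step_mm = interpolation_step_mm,
                 max_gamma = max_gamma),
            class = "mc_gamma_criteria")
}

#' Global gamma map and passing rate
#'
#' For each reference voxel at or above the low-dose threshold, the gamma
#' index is the minimum over evaluated positions within the search radius of
#' `sqrt(dist^2 / dta^2 + (D_eval - D_ref)^2 / dD^2)`, with `dD` the dose
#' criterion times the maximum reference dose (global normalization) and
#' the evaluated dose interpolated trilinearly on the search grid. The pass
#' rate is the percentage of evaluated voxels with gamma <= 1 (a 1e-9
#' relative tolerance keeps exact-boundary voxels passing).
#'
#' @param reference Reference dose [mc_volume()] (max > 0).
#' @param evaluated Evaluated dose [mc_volume()] on the same grid.
#' @param criteria A [gamma_criteria()].
#' @return A list of class `mc_gamma_result`: `gamma` (3D array, `NA` below
#'   threshold), `pass_rate` (%), `n_evaluated`, `criteria`.
#' @examples
#' ref <- mc_volume(array(1, c(16, 16, 8)))
#' identical_pass <- gamma_map(ref, ref, gamma_criteria(2, 2))
#' identical_pass$pass_rate
#' @export
gamma_map <- function(reference, evaluated, criteria) {
  stopifnot(inherits(criteria, "mc_gamma_criteria"))
  if (!same_grid(reference, evaluated)) stopf("reference/evaluated grid mismatch")
  if (max(reference$values) <= 0) stopf("reference distribution is all zero")
  d <- dim(reference$values)
  g <- .gamma_core(as.numeric(reference$values), as.numeric(evaluated$values),
                   d, reference$voxel_size * 10, # cm -> mm
                   criteria$dose_percent / 100, criteria$distance_mm,
                   criteria$low_dose_threshold / 100,
                   criteria$search_radius_mm, criteria$interpolation_step_mm,
                   criteria$max_gamma)
  g <- array(g, d)
  evaluated_mask <- !is.na(g)
  pass <- g[evaluated_mask] <= 1 + 1e-9
  structure(list(gamma = g, pass_rate = 100 * mean(pass),
                 n_evaluated = sum(evaluated_mask), criteria = criteria),
            class = "mc_gamma_result")
}

#' @export
print.mc_gamma_result <- function(x, ...) {
  cat(sprintf("<mc_gamma_result> %.1f%%/%g mm: pass rate %.2f%% over %d voxels\n",
              x$criteria$dose_percent, x$criteria$distance_mm,
              x$pass_rate, x$n_evaluated))
  invisible(x)
}

#' @export
glance.mc_gamma_result <- function(x, ...) {
  tibble::tibble(dose_percent = x$criteria$dose_percent,
                 distance_mm = x$criteria$distance_mm,
                 low_dose_threshold = x$criteria$low_dose_threshold,
                 pass_rate = x$pass_rate, n_evaluated = x$n_evaluated,
                 mean_gamma = mean(x$gamma, na.rm = TRUE),
                 max_gamma = max(x$gamma, na.rm = TRUE))
}

#' Plot a mid-volume slice of a gamma map
#'
#' @param object An `mc_gamma_result`.
#' @param slice z index (default mid-volume).
#' @param ... Unused.
#' @return A ggplot; failing voxels (gamma > 1) appear above the midpoint
#'   of the fill scale.
#' @export
autoplot.mc_gamma_result <- function(object, slice = NULL, ...) {
  d <- dim(object$gamma)
  if (is.null(slice)) slice <- (d[3] + 1L) %/% 2L
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$gamma <- as.vector(object$gamma[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$gamma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "red",
                                  midpoint = 1, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("gamma %g%%/%g mm, slice %d (pass %.1f%%)",
                                  object$criteria$dose_percent,
                                  object$criteria$distance_mm, slice,
                                  object$pass_rate))
}
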