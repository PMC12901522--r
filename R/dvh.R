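#' Cumulative dose-volume histogram
#'
#' `V(d)` is the percentage of structure voxels receiving at least dose `d`,
#' evaluated at bin edges from 0 to one bin above the maximum structure
#' dose. The curve starts at 100%, is non-increasing and ends at 0%.
#'
#' @param dose An [mc_volume()] (or 3D array).
#' @param structure_mask Logical array selecting the structure (non-empty).
#' @param bin_width Bin width in Gy (default 0.01).
#' @param label Structure label carried in the result.
#' @return A list of class `mc_dvh`: `dose` (bin edges, Gy), `volume`
#'   (cumulative %, same length), `label`, `mean_dose`.
#' @export
dvh <- function(dose, structure_mask, bin_width = 0.01, label = "structure") {
  vals <- as_volume_values(dose)
  if (!identical(dim(structure_mask), dim(vals))) stopf("mask geometry mismatch")
  dv <- vals[structure_mask]
  if (length(dv) == 0L) stopf("empty structure")
  check_number(bin_width, "bin_width", lower = 0, allow_zero = FALSE)
  edges <- seq(0, max(dv) + bin_width, by = bin_width)
  vol <- vapply(edges, function(d) 100 * mean(dv >= d), numeric(1))
  structure(list(dose = edges, volume = vol, label = label,
                 mean_dose = mean(dv)),
            class = "mc_dvh")
}

#' @export
print.mc_dvh <- function(x, ...) {
  cat(sprintf("<mc_dvh> %s: %d bins, mean dose %.4g Gy\n",
              x$label, length(x$dose), x$mean_dose))
  invisible(x)
}

#' DVH curve as a tibble
#'
#' @param x An `mc_dvh`.
#' @param ... Unused.
#' @return Tibble with `dose` (Gy) and `volume` (%).
#' @export
tidy.mc_dvh <- function(x, ...) {
  tibble::tibble(structure = x$label, dose = x$dose, volume = x$volume)
}

#' @export
glance.mc_dvh <- function(x, ...) {
  tibble::tibble(structure = x$label, mean_dose = x$mean_dose,
                 d98 = dose_at_volume(x, 98), d50 = dose_at_volume(x, 50),
                 d2 = dose_at_volume(x, 2))
}

#' Plot one or more DVH curves
#'
#' @param object An `mc_dvh` or a list of them.
#' @param ... Further `mc_dvh` objects.
#' @return A ggplot.
#' @export
autoplot.mc_dvh <- function(object, ...) {
  curves <- c(list(object), Filter(function(o) inherits(o, "mc_dvh"), list(...)))
  df <- dplyr::bind_rows(lapply(curves, tidy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$volume,
                                   colour = .data$structure)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "dose [Gy]", y = "volume [%]", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100))
}

#' Dose-volume parameters
#'
#' `dose_at_volume()` returns Dx%: the largest dose received by at least x%
#' of the structure, linearly interpolated between DVH bins. D98% and D2%
#' are the near-minimum and near-maximum dose; Dm (mean dose) is carried on
#' the curve object.
#'
#' @param curve An `mc_dvh`.
#' @param volume_percent Percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(curve, volume_percent) {
  stopifnot(inherits(curve, "mc_dvh"))
  if (volume_percent <= 0 || volume_percent > 100)
    stopf("`volume_percent` must be in (0, 100]")
  v <- curve$volume
  d <- curve$dose
  # V is non-increasing; find the last bin with V >= x and interpolate
  idx <- which(v >= volume_percent)
  if (length(idx) == 0L) return(0)
  i <- max(idx)
  if (i == length(v) || v[i] == volume_percent) return(d[i])
  # interpolate between (d[i], v[i]) and (d[i+1], v[i+1])
  if (v[i] == v[i + 1L]) return(d[i])
  d[i] + (d[i + 1L] - d[i]) * (v[i] - volume_percent) / (v[i] - v[i + 1L])
}

#' @rdname dose_at_volume
#' @param dose An [mc_volume()] (or array).
#' @param mask Logical structure mask.
#' @param dose_level Absolute dose level in Gy (e.g. x% of the prescription).
#' @return `volume_at_dose()`: percentage of the structure receiving at
#'   least `dose_level`.
#' @export
volume_at_dose <- function(dose, mask, dose_level) {
  vals <- as_volume_values(dose)
  dv <- vals[mask]
  if (length(dv) == 0L) stopf("empty structure")
  100 * mean(dv >= dose_level)
}
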