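#' Specify a CT-like phantom
#'
#' Describes a water-equivalent ellipsoidal body inside an air-filled grid,
#' with optional low-density (lung-like, -700 HU) and high-density
#' (bone-like, +700 HU) ellipsoidal inserts. Stands in for clinical CTs.
#'
#' @param shape Length-3 integer, grid size in voxels (each >= 16).
#' @param voxel_size Length-3 numeric, cm (default 0.25).
#' @param body_semiaxes Length-3 numeric, ellipsoid semi-axes in cm.
#' @param center Length-3 numeric, body centre in cm relative to the grid
#'   origin; default is the grid centre.
#' @param inserts List of inserts, each `list(type = "lung"|"bone",
#'   center = cm triple, semiaxes = cm triple)`.
#' @param hu_noise_sd Standard deviation of optional Gaussian HU texture
#'   added inside the body (default 0: exact nominal HU).
#' @return A list of class `mc_phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_size = c(0.25, 0.25, 0.25),
                         body_semiaxes, center = NULL, inserts = list(),
                         hu_noise_sd = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stopf("`shape` must be three integers >= 16", class = "mcdose_spec_error")
  voxel_size <- as.numeric(voxel_size)
  extent <- shape * voxel_size
  if (is.null(center)) center <- extent / 2
  body_semiaxes <- as.numeric(body_semiaxes)
  if (any(center - body_semiaxes < 0) || any(center + body_semiaxes > extent))
    stopf("body ellipsoid (semi-axes %s cm) exceeds the grid extent %s cm",
          paste(signif(body_semiaxes, 3), collapse = "x"),
          paste(signif(extent, 3), collapse = "x"),
          class = "mcdose_spec_error")
  for (ins in inserts) {
    if (!ins$type %in% c("lung", "bone"))
      stopf("unknown insert type '%s'", ins$type, class = "mcdose_spec_error")
  }
  structure(list(shape = shape, voxel_size = voxel_size,
                 body_semiaxes = body_semiaxes, center = center,
                 inserts = inserts, hu_noise_sd = hu_noise_sd),
            class = "mc_phantom_spec")
}

#' Generate a CT-like phantom
#'
#' Realizes a [phantom_spec()] as a Hounsfield-unit grid plus body mask.
#' The body is water-equivalent (HU 0), inserts are -700 HU (lung-like) or
#' +700 HU (bone-like), everything outside the body is air (-1000 HU). The
#' body mask is derived as HU > -400.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed (used only when `hu_noise_sd > 0`).
#' @return An object of class `mc_phantom` with fields `hu` (3D array),
#'   `voxel_size`, `origin`, `body_mask` (3D logical array).
#' @examples
#' ph <- generate_phantom(phantom_spec(c(24, 24, 16), body_semiaxes = c(2.4, 2.4, 1.6)))
#' sum(ph$body_mask)
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mc_phantom_spec"))
  d <- spec$shape
  h <- spec$voxel_size
  # voxel-centre coordinates, origin at the first voxel centre = h/2
  origin <- h / 2
  cx <- origin[1] + (seq_len(d[1]) - 1) * h[1]
  cy <- origin[2] + (seq_len(d[2]) - 1) * h[2]
  cz <- origin[3] + (seq_len(d[3]) - 1) * h[3]

  inside_ellipsoid <- function(center, semi) {
    ex <- ((cx - center[1]) / semi[1])^2
    ey <- ((cy - center[2]) / semi[2])^2
    ez <- ((cz - center[3]) / semi[3])^2
    outer(outer(ex, ey, `+`), ez, `+`) <= 1
  }

  body <- inside_ellipsoid(spec$center, spec$body_semiaxes)
  if (!any(body)) stopf("phantom body contains no voxels", class = "mcdose_spec_error")
  hu <- array(-1000, d)
  hu[body] <- 0
  for (ins in spec$inserts) {
    m <- inside_ellipsoid(ins$center, ins$semiaxes) & body
    hu[m] <- if (ins$type == "lung") -700 else 700
  }
  if (spec$hu_noise_sd > 0) {
    set.seed(as.integer(seed))
    hu[body] <- hu[body] + rnorm(sum(body), 0, spec$hu_noise_sd)
  }
  structure(list(hu = hu, voxel_size = h, origin = origin,
                 body_mask = hu > -400),
            class = "mc_phantom")
}

#' @export
print.mc_phantom <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<mc_phantom> %d x %d x %d voxels at %.3g cm, %d body voxels\n",
              d[1], d[2], d[3], x$voxel_size[1], sum(x$body_mask)))
  invisible(x)
}

# voxel-centre coordinate of a (1-based) voxel index triple, in cm
voxel_center <- function(phantom, idx) {
  phantom$origin + (as.numeric(idx) - 1) * phantom$voxel_size
}

#' Radiological depth along a source-to-voxel ray
#'
#' Density-weighted path length (g/cm^2) from an external source point to
#' the centre of a target voxel, by ray marching with step at most half the
#' smallest voxel dimension. Density is mapped linearly from HU
#' (-1000 -> 0 g/cm^3, 0 -> 1 g/cm^3, clamped at 0).
#'
#' @param phantom An `mc_phantom`.
#' @param source Length-3 numeric, source position in cm (outside the body).
#' @param target_voxel Length-3 integer voxel index (1-based).
#' @param step Optional marching step in cm; at most half the smallest
#'   voxel dimension (the contract), defaulting to one quarter of it for a
#'   comfortable quadrature margin at tissue interfaces.
#' @return Radiological depth in g/cm^2.
#' @export
radiological_depth <- function(phantom, source, target_voxel, step = NULL) {
  stopifnot(inherits(phantom, "mc_phantom"))
  d <- dim(phantom$hu)
  target_voxel <- as.integer(target_voxel)
  if (any(target_voxel < 1L) || any(target_voxel > d))
    stopf("`target_voxel` outside the grid")
  src_idx <- floor((as.numeric(source) - (phantom$origin - phantom$voxel_size / 2)) /
                     phantom$voxel_size) + 1
  if (all(src_idx >= 1) && all(src_idx <= d) &&
      phantom$body_mask[src_idx[1], src_idx[2], src_idx[3]])
    stopf("`source` must lie outside the body")
  if (is.null(step)) step <- min(phantom$voxel_size) / 4
  if (step > min(phantom$voxel_size) / 2)
    stopf("`step` must not exceed half the smallest voxel dimension")
  tgt <- voxel_center(phantom, target_voxel)
  if (sqrt(sum((tgt - as.numeric(source))^2)) == 0)
    stopf("degenerate ray: source coincides with target")
  .rad_depth_single(as.numeric(phantom$hu), d, phantom$voxel_size,
                    phantom$origin, as.numeric(source), tgt, step)
}

# radiological depth from one source to every voxel centre (engine workhorse)
rad_depth_field <- function(phantom, source, step = NULL) {
  if (is.null(step)) step <- min(phantom$voxel_size) / 2
  d <- dim(phantom$hu)
  array(.rad_depth_field(as.numeric(phantom$hu), d, phantom$voxel_size,
                         phantom$origin, as.numeric(source), step), d)
}
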