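# Shared small fixtures, built in code. Sizes are kept small so the whole
# suite stays fast; dose grids reuse the deterministic engine.

water_phantom <- function(shape = c(32, 32, 24), semi = c(3.5, 3.5, 2.5)) {
  generate_phantom(phantom_spec(shape, body_semiaxes = semi))
}

small_dose_case <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ph <- water_phantom()
      plan <- random_arc_plan(ph, n_control_points = 4, seed = 2)
      memo <<- list(phantom = ph, plan = plan,
                    dose = compute_clean_dose(ph, plan))
    }
    memo
  }
})

random_volume <- function(dim3, seed, voxel_size = c(0.25, 0.25, 0.25)) {
  set.seed(seed)
  mc_volume(array(runif(prod(dim3)), dim3), voxel_size = voxel_size)
}

# smooth random dose-like reference with a compact high-dose region, so the
# 10% threshold selects a moderate number of voxels
smooth_dose_volume <- function(dim3 = c(16, 16, 16), seed = 1) {
  set.seed(seed)
  cx <- seq_len(dim3[1]); cy <- seq_len(dim3[2]); cz <- seq_len(dim3[3])
  c0 <- (dim3 + 1) / 2 + runif(3, -2, 2)
  w <- runif(3, 3, 6)
  bump <- outer(outer(exp(-((cx - c0[1]) / w[1])^2),
                      exp(-((cy - c0[2]) / w[2])^2)),
                exp(-((cz - c0[3]) / w[3])^2))
  mc_volume(bump + 0.02 * array(runif(prod(dim3)), dim3))
}
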