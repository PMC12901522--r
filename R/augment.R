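#' Augmentation ranges for arc-plan variation
#'
#' The augmentation roster re-randomizes, per variant: the MU weight of each
#' control point (positive multiplicative jitter, renormalized to a
#' randomized total MU), the beam energy, the isocenter position (shift
#' bounded per axis and rejected-resampled until inside the body) and the
#' collimator rotation. Aperture shapes are never modified.
#'
#' @param iso_shift Length-3 non-negative bounds (cm) for the isocenter
#'   shift per axis; must not exceed the (9, 5, 10) cm envelope.
#' @param mu_jitter Two-element range for the per-control-point
#'   multiplicative MU jitter (default `c(0.2, 2)`).
#' @param total_mu_factor Two-element range for the total-MU rescaling
#'   factor (default `c(0.5, 2)`).
#' @param collimator Two-element range in degrees for the collimator
#'   rotation draw (default `c(0, 360)`).
#' @param energies Energy labels to draw uniformly from, or `NULL` to keep
#'   each base arc's energy (default `c(6, 10, 15)`).
#' @return A list of class `mc_aug_ranges`.
#' @export
augmentation_ranges <- function(iso_shift = c(9, 5, 10), mu_jitter = c(0.2, 2),
                                total_mu_factor = c(0.5, 2),
                                collimator = c(0, 360),
                                energies = c(6, 10, 15)) {
  iso_shift <- as.numeric(iso_shift)
  if (length(iso_shift) != 3L || any(iso_shift < 0) ||
      any(iso_shift > c(9, 5, 10) + 1e-9))
    stopf("`iso_shift` must be within the (9, 5, 10) cm per-axis envelope")
  if (any(mu_jitter <= 0) || diff(mu_jitter) < 0)
    stopf("`mu_jitter` must be a positive, non-decreasing range")
  if (!is.null(energies) && !all(energies %in% BEAM_ENERGIES))
    stopf("`energies` must be a subset of %s", paste(BEAM_ENERGIES, collapse = ", "))
  structure(list(iso_shift = iso_shift, mu_jitter = as.numeric(mu_jitter),
                 total_mu_factor = as.numeric(total_mu_factor),
                 collimator = as.numeric(collimator), energies = energies),
            class = "mc_aug_ranges")
}

zero_width_ranges <- function() {
  augmentation_ranges(iso_shift = c(0, 0, 0), mu_jitter = c(1, 1),
                      total_mu_factor = c(1, 1), collimator = c(0, 0),
                      energies = NULL)
}

draw_variant <- function(plan, phantom, ranges) {
  cps <- plan$control_points
  w <- vapply(cps, `[[`, numeric(1), "mu_weight")
  jitter <- runif(length(w), ranges$mu_jitter[1], ranges$mu_jitter[2])
  total_new <- plan$total_mu * runif(1, ranges$total_mu_factor[1],
                                     ranges$total_mu_factor[2])
  w_new <- w * jitter
  w_new <- w_new * total_new / sum(w_new)
  energy <- if (is.null(ranges$energies)) cps[[1]]$energy
            else ranges$energies[sample.int(length(ranges$energies), 1)]
  coll <- runif(1, ranges$collimator[1], ranges$collimator[2])

  # isocenter shift: rejection-resampled until inside the body
  d <- dim(phantom$hu)
  iso_new <- NULL
  shift <- c(0, 0, 0)
  for (attempt in seq_len(100)) {
    shift <- runif(3, -ranges$iso_shift, ranges$iso_shift)
    cand <- plan$isocenter + shift
    idx <- floor((cand - (phantom$origin - phantom$voxel_size / 2)) /
                   phantom$voxel_size) + 1
    if (all(idx >= 1) && all(idx <= d) &&
        phantom$body_mask[idx[1], idx[2], idx[3]]) {
      iso_new <- cand
      break
    }
  }
  if (is.null(iso_new))
    stopf("no isocenter shift inside the body after 100 attempts")

  new_cps <- lapply(seq_along(cps), function(i) {
    cp <- cps[[i]]
    cp$mu_weight <- w_new[i]
    cp$energy <- energy
    cp$collimator_rotation <- coll
    cp
  })
  list(plan = arc_plan(new_cps, isocenter = iso_new, sad = plan$sad),
       energy = energy, collimator = coll, iso_shift = shift,
       mu_weights = w_new, total_mu = total_new)
}

#' Build the augmentation roster of plan variants
#'
#' Expands `length(base_arcs) * factor` plan variants (each base arc is
#' paired with a phantom) and records every random draw in a roster tibble
#' that round-trips losslessly through [write_roster()] / [read_roster()].
#' No dose is computed; see [build_augmented_dataset()] for the full
#' phantom/dose-pair triplets.
#'
#' @param base_arcs List of `mc_arc_plan`s.
#' @param phantoms List of `mc_phantom`s.
#' @param factor Augmentation factor (>= 1).
#' @param ranges An [augmentation_ranges()].
#' @param seed Integer seed.
#' @param phantom_assignment Integer vector mapping each base arc to a
#'   phantom index; default cycles through the phantoms.
#' @return A list with `plans` (list of variant `mc_arc_plan`s),
#'   `phantom_ids` (integer vector) and `roster` (tibble, one row per
#'   variant).
#' @examples
#' ph <- generate_phantom(phantom_spec(c(24, 24, 16), body_semiaxes = c(2.4, 2.4, 1.6)))
#' arcs <- list(random_arc_plan(ph, 4, seed = 1))
#' aug <- augment_plans(arcs, list(ph), factor = 3,
#'                      ranges = augmentation_ranges(iso_shift = c(1, 1, 1)))
#' nrow(aug$roster)
#' @export
augment_plans <- function(base_arcs, phantoms, factor, ranges = augmentation_ranges(),
                          seed = 1L, phantom_assignment = NULL) {
  if (factor < 1) stopf("`factor` must be >= 1")
  stopifnot(inherits(ranges, "mc_aug_ranges"))
  n_arcs <- length(base_arcs)
  if (is.null(phantom_assignment))
    phantom_assignment <- rep_len(seq_along(phantoms), n_arcs)
  stopifnot(length(phantom_assignment) == n_arcs)
  set.seed(as.integer(seed))

  plans <- vector("list", n_arcs * factor)
  phantom_ids <- integer(n_arcs * factor)
  rows <- vector("list", n_arcs * factor)
  q <- 0L
  for (i in seq_len(n_arcs)) {
    ph <- phantoms[[phantom_assignment[i]]]
    for (j in seq_len(factor)) {
      q <- q + 1L
      v <- draw_variant(base_arcs[[i]], ph, ranges)
      plans[[q]] <- v$plan
      phantom_ids[q] <- phantom_assignment[i]
      rows[[q]] <- tibble::tibble(
        triplet = q, base_arc = i, variant = j,
        phantom = phantom_assignment[i],
        energy = v$energy, collimator_rotation = v$collimator,
        iso_shift_x = v$iso_shift[1], iso_shift_y = v$iso_shift[2],
        iso_shift_z = v$iso_shift[3],
        isocenter_x = v$plan$isocenter[1], isocenter_y = v$plan$isocenter[2],
        isocenter_z = v$plan$isocenter[3],
        total_mu = v$total_mu, mu_weights = list(v$mu_weights))
    }
  }
  list(plans = plans, phantom_ids = phantom_ids,
       roster = dplyr::bind_rows(rows))
}

#' Generate the full augmented dataset of phantom/dose-pair triplets
#'
#' Runs [augment_plans()] and, for every variant, computes the clean dose
#' with the deterministic engine and draws a noisy realization at
#' `histories_high` with the given noise model. Exactly
#' `length(base_arcs) * factor` triplets are produced.
#'
#' @inheritParams augment_plans
#' @param histories_high Particle-history count of the noisy member.
#' @param model An [noise_model()].
#' @param depth_step Passed to [compute_clean_dose()].
#' @return A list with `triplets` (each `list(phantom_id, plan, pair)` where
#'   `pair` is an `mc_dose_pair`), `phantoms`, and `roster`.
#' @export
build_augmented_dataset <- function(base_arcs, phantoms, factor,
                                    ranges = augmentation_ranges(), seed = 1L,
                                    histories_high = 1.5e6,
                                    model = noise_model(),
                                    phantom_assignment = NULL,
                                    depth_step = NULL) {
  aug <- augment_plans(base_arcs, phantoms, factor, ranges, seed,
                       phantom_assignment)
  n <- length(aug$plans)
  triplets <- vector("list", n)
  for (q in seq_len(n)) {
    ph <- phantoms[[aug$phantom_ids[q]]]
    clean <- compute_clean_dose(ph, aug$plans[[q]], depth_step = depth_step)
    pair_seed <- derive_seed(seed, paste0("noise/", q))
    noisy <- sample_noisy_dose(clean, histories_high, model, seed = pair_seed)
    triplets[[q]] <- list(phantom_id = aug$phantom_ids[q], plan = aug$plans[[q]],
                          pair = dose_pair(clean, noisy, histories_high, pair_seed))
  }
  list(triplets = triplets, phantoms = phantoms, roster = aug$roster)
}

#' Paired clean/noisy dose grids
#'
#' @param clean,noisy [mc_volume()] dose grids on the same geometry.
#' @param histories Particle-history count of the noisy member.
#' @param seed Seed used for the noisy draw.
#' @return A list of class `mc_dose_pair`.
#' @export
dose_pair <- function(clean, noisy, histories, seed) {
  stopifnot(inherits(clean, "mc_volume"), inherits(noisy, "mc_volume"))
  if (!same_grid(clean, noisy)) stopf("clean and noisy grids differ")
  if (min(clean$values) < 0 || min(noisy$values) < 0)
    stopf("doses must be non-negative")
  structure(list(clean = clean, noisy = noisy, histories = histories,
                 seed = seed),
            class = "mc_dose_pair")
}

#' Write / read an augmentation roster manifest
#'
#' JSON round-trip is lossless: numeric values are serialized at full
#' precision.
#'
#' @param roster Roster tibble from [augment_plans()].
#' @param path JSON file path.
#' @return `path` (write) or the roster tibble (read).
#' @export
write_roster <- function(roster, path) {
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(roster, path, digits = I(17), dataframe = "columns")
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mw <- obj$mu_weights
  obj$mu_weights <- if (is.matrix(mw)) {
    lapply(seq_len(nrow(mw)), function(i) as.numeric(mw[i, ]))
  } else {
    lapply(mw, as.numeric)
  }
  tibble::as_tibble(obj)
}
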