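# Streak-field components shared by injection and calibration.
#
# Rays alternate hyper-/hypo-dense around the stem axis: the angular part is
# sign(cos(n_streaks * theta + phi)) * |cos(n_streaks * theta + phi)|^m,
# where the sharpness exponent m >= 0 narrows the rays (large m gives thin
# needle-like streaks with steep flanks). The envelope decays in-plane as
# 1 / (1 + d / decay_mm) with in-plane distance d from the stem axis and
# axially as 1 / (1 + |z - z_tip| / axial_decay_mm) anchored at the distal
# stem tip, so the slice-wise artifact load decays with distance from the
# tip. phi is a random ray rotation drawn from `seed`.
#
# Returns signed angular base and non-negative envelope as separate arrays
# (both 0 where no perturbation applies), so the exponent can be calibrated
# in closed form without recomputing geometry.
streak_components <- function(vol, n_streaks, decay_mm, axial_decay_mm,
                              seed) {
  g <- phantom_geometry(vol$spec)
  codes <- material_codes()
  phi <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  theta <- atan2(g$yg, g$xg)
  r <- sqrt(g$xg^2 + g$yg^2)
  ang2d <- cos(n_streaks * theta + phi)
  base <- array(0, g$dim)
  env <- array(0, g$dim)
  metal_slices <- which(apply(vol$labels == codes[["metal"]], 3, any))
  radial <- 1 / (1 + r / decay_mm)
  for (k in metal_slices) {
    az <- 1 / (1 + abs(g$z[k] - vol$spec$z_tip_mm) / axial_decay_mm)
    e <- az * radial
    lab <- vol$labels[, , k]
    tissue <- lab == codes[["water"]] | lab == codes[["cortical_bone"]] |
      lab == codes[["bone_marrow"]]
    e[!tissue] <- 0
    base[, , k] <- ang2d
    env[, , k] <- e
  }
  list(base = base, env = env)
}

# unit-amplitude perturbation field for a given sharpness exponent
streak_field <- function(vol, n_streaks, decay_mm, axial_decay_mm, seed,
                         sharpness = 1) {
  cmp <- streak_components(vol, n_streaks, decay_mm, axial_decay_mm, seed)
  sign(cmp$base) * abs(cmp$base)^sharpness * cmp$env
}

#' Inject synthetic streak artifacts around the metal stem
#'
#' Adds alternating bright/dark angular rays emanating from the stem axis in
#' every slice containing metal. The perturbation at a voxel is
#' `amplitude_hu * sign(c) * |c|^sharpness / ((1 + d/decay_mm) *
#' (1 + |z - z_tip|/axial_decay_mm))` with `c = cos(n_streaks * theta +
#' phi)`, `d` the in-plane distance from the stem axis and `z_tip` the
#' distal stem tip. Voxels whose injected perturbation exceeds
#' `truth_cutoff_hu` in magnitude are recorded as ground-truth artifacts, so
#' downstream recovery of the artifact percentage can be validated.
#'
#' The streak model is a deliberately simple analytic stand-in for
#' beam-hardening physics: it reproduces the behaviour that matters for
#' validating the quantification pipeline — artifact load decaying with
#' distance from the prosthesis — without simulating projections. The
#' `sharpness` exponent controls how abruptly a ray's flank crosses the
#' truth cutoff; large values keep the noise-smeared transition band small,
#' which is what makes ground-truth recovery well-posed.
#'
#' @param vol a clean `labeled_volume` from [build_phantom()].
#' @param amplitude_hu peak perturbation amplitude at the stem surface (HU);
#'   either 0 (no-op) or greater than `truth_cutoff_hu`.
#' @param n_streaks number of hyper/hypo ray pairs around the stem.
#' @param decay_mm in-plane decay length (mm).
#' @param axial_decay_mm axial decay length from the stem tip (mm).
#' @param sharpness angular exponent (>= 0); 1 gives plain cosine rays.
#' @param truth_cutoff_hu magnitude above which an injected perturbation is
#'   recorded in `artifact_truth`; pair it with `k_sd` times the noise SD of
#'   the threshold-source series so that recovery is well-posed.
#' @param seed integer seed controlling the random ray rotation.
#' @return the input `labeled_volume` with perturbed `image`, populated
#'   `artifact_truth` and the `seed` recorded.
#' @export
inject_artifacts <- function(vol, amplitude_hu, n_streaks = 16,
                             decay_mm = 20, axial_decay_mm = 60,
                             sharpness = 1, truth_cutoff_hu = 100,
                             seed = 1) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (!any(vol$labels == material_codes()[["metal"]])) {
    stopf("volume contains no metal: nothing to emanate streaks from")
  }
  if (!is_len(amplitude_hu, 1) || amplitude_hu < 0) {
    stopf("'amplitude_hu' must be a non-negative HU value")
  }
  if (amplitude_hu > 0 && amplitude_hu <= truth_cutoff_hu) {
    stopf("'amplitude_hu' must exceed 'truth_cutoff_hu' (or be 0)")
  }
  if (!is_len(sharpness, 1) || sharpness < 0) {
    stopf("'sharpness' must be non-negative")
  }
  if (amplitude_hu == 0) return(vol)
  pert <- amplitude_hu *
    streak_field(vol, n_streaks, decay_mm, axial_decay_mm, seed, sharpness)
  vol$image$data <- vol$image$data + pert
  vol$artifact_truth <- abs(pert) > truth_cutoff_hu
  vol$seed <- as.integer(seed)
  vol
}

#' Calibrate streak parameters to hit a target ground-truth fraction
#'
#' The ground-truth artifact fraction produced by [inject_artifacts()] is an
#' emergent function of amplitude, sharpness, cutoff and geometry. Both
#' calibrations below are exact closed forms over the voxels of a target
#' region (deterministic given `seed`):
#'
#' * `calibrate_streak_amplitude()` solves for the amplitude at fixed
#'   sharpness: `A = truth_cutoff_hu / q` with `q` the `(1 - target/100)`
#'   quantile of the unit-field magnitudes.
#' * `calibrate_streak_sharpness()` solves for the angular exponent at fixed
#'   amplitude: a voxel with angular base `c` and envelope `e` is truth iff
#'   `m < (log(cutoff/A) - log(e)) / log|c|`, so the exponent is the
#'   `(1 - target/100)` quantile of that per-voxel bound. Preferred for
#'   recovery studies because the amplitude can stay far above the cutoff
#'   (e.g. 10x), keeping the noise-smeared boundary band negligible.
#'
#' @param vol clean `labeled_volume`.
#' @param mask [ct_mask()] over which the truth fraction is defined (for
#'   example bone marrow within the VOI).
#' @param target_percent requested ground-truth artifact percentage in
#'   `mask` (0-100, exclusive).
#' @inheritParams inject_artifacts
#' @return amplitude in HU, or the sharpness exponent.
#' @export
calibrate_streak_amplitude <- function(vol, mask, target_percent,
                                       n_streaks = 16, decay_mm = 20,
                                       axial_decay_mm = 60, sharpness = 1,
                                       truth_cutoff_hu = 100, seed = 1) {
  u <- calib_field_values(vol, mask, target_percent, n_streaks, decay_mm,
                          axial_decay_mm, seed)
  u <- abs(sign(u$base) * abs(u$base)^sharpness * u$env)
  q <- unname(quantile(u, 1 - target_percent / 100, names = FALSE))
  if (q <= 0) {
    stopf(paste0("target truth fraction %.1f%% is not achievable: too few ",
                 "voxels of the region are reached by streaks"),
          target_percent)
  }
  truth_cutoff_hu / q
}

#' @rdname calibrate_streak_amplitude
#' @export
calibrate_streak_sharpness <- function(vol, mask, target_percent,
                                       amplitude_hu, n_streaks = 16,
                                       decay_mm = 20, axial_decay_mm = 60,
                                       truth_cutoff_hu = 100, seed = 1) {
  if (amplitude_hu <= truth_cutoff_hu) {
    stopf("'amplitude_hu' must exceed 'truth_cutoff_hu'")
  }
  u <- calib_field_values(vol, mask, target_percent, n_streaks, decay_mm,
                          axial_decay_mm, seed)
  b <- pmin(abs(u$base), 1 - 1e-12)
  # per-voxel largest exponent at which the voxel still exceeds the cutoff
  bound <- (log(truth_cutoff_hu / amplitude_hu) - log(u$env)) / log(b)
  bound[u$env <= 0] <- 0
  bound[abs(u$base) >= 1 - 1e-12 & u$env * amplitude_hu > truth_cutoff_hu] <-
    Inf
  bound[bound < 0] <- 0
  m <- unname(quantile(bound, 1 - target_percent / 100, names = FALSE))
  if (!is.finite(m) || m <= 0) {
    stopf(paste0("target truth fraction %.1f%% is not achievable at ",
                 "amplitude %.1f HU in this region"),
          target_percent, amplitude_hu)
  }
  m
}

# shared validation + field extraction over the calibration mask
calib_field_values <- function(vol, mask, target_percent, n_streaks,
                               decay_mm, axial_decay_mm, seed) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(mask, "ct_mask"))
  assert_same_grid(vol$image, mask, "volume and calibration mask")
  if (!is_len(target_percent, 1) || target_percent <= 0 ||
      target_percent >= 100) {
    stopf("'target_percent' must be strictly between 0 and 100")
  }
  if (!sum(mask$data)) stopf("calibration mask is empty")
  cmp <- streak_components(vol, n_streaks, decay_mm, axial_decay_mm, seed)
  list(base = cmp$base[mask$data], env = cmp$env[mask$data])
}
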