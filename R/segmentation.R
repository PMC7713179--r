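#' Reference-region HU statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of the CT numbers
#' inside a mask — the reference statistics from which the artifact
#' thresholds are derived.
#'
#' @param vol a [ct_volume()].
#' @param mask a non-empty [ct_mask()] on the same grid.
#' @param material material name carried along for bookkeeping.
#' @param source_series id of the series the statistics came from.
#' @return object of class `material_stats`: list with `material`,
#'   `mean_hu`, `sd_hu`, `n_voxels`, `source_series`.
#' @examples
#' v <- ct_volume(array(c(0, 2, 5, 5), c(2, 2, 1)), c(1, 1, 1))
#' m <- ct_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)), c(1, 1, 1))
#' region_stats(v, m)
#' @export
region_stats <- function(vol, mask, material = NA_character_,
                         source_series = NA_character_) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "ct_mask"))
  assert_same_grid(vol, mask, "volume and mask")
  vals <- vol$data[mask$data]
  if (length(vals) < 2) {
    stopf("mask must select at least 2 voxels (got %d)", length(vals))
  }
  structure(list(material = material, mean_hu = mean(vals),
                 sd_hu = sd(vals), n_voxels = length(vals),
                 source_series = source_series),
            class = "material_stats")
}

#' @export
print.material_stats <- function(x, ...) {
  cat(sprintf("<material_stats> %s: mean %.2f HU, SD %.2f HU (n = %d%s)\n",
              x$material, x$mean_hu, x$sd_hu, x$n_voxels,
              if (is.na(x$source_series)) ""
              else paste0(", from ", x$source_series)))
  invisible(x)
}

#' Construct material stats directly from known values
#'
#' Convenience constructor for feeding published or externally measured
#' mean/SD values into [compute_thresholds()] or [cnr()].
#'
#' @param mean_hu,sd_hu mean and SD in HU.
#' @param material,n_voxels,source_series optional bookkeeping.
#' @return a `material_stats` object.
#' @export
material_stats <- function(mean_hu, sd_hu, material = NA_character_,
                           n_voxels = NA_integer_,
                           source_series = NA_character_) {
  if (!is_len(mean_hu, 1) || !is_len(sd_hu, 1) || sd_hu < 0) {
    stopf("'mean_hu' must be finite and 'sd_hu' non-negative")
  }
  structure(list(material = material, mean_hu = mean_hu, sd_hu = sd_hu,
                 n_voxels = n_voxels, source_series = source_series),
            class = "material_stats")
}

#' Mean +/- k SD artifact thresholds
#'
#' Converts reference statistics into the lower/upper HU bounds that define
#' "normal" tissue: `mean - k_sd * SD` and `mean + k_sd * SD`. At the
#' default `k_sd = 3` and under a normal distribution of CT numbers the
#' bounds encompass 99.7% of artifact-free tissue; everything outside is
#' classified as metal artifact.
#'
#' @param stats a `material_stats` object (from [region_stats()] or
#'   [material_stats()]).
#' @param k_sd positive multiplier of the SD (default 3).
#' @param tube_potential_kvp optional kVp recorded with the pair (thresholds
#'   are tube-potential specific because CT numbers are).
#' @return object of class `threshold_pair` with `lower_hu`, `upper_hu`,
#'   `k_sd`, `material`, `tube_potential_kvp`, `source_series`.
#' @examples
#' compute_thresholds(material_stats(679.70, 80.93, "cortical_bone"))
#' @export
compute_thresholds <- function(stats, k_sd = 3, tube_potential_kvp = NA) {
  stopifnot(inherits(stats, "material_stats"))
  if (!is_len(k_sd, 1, min = 0)) stopf("'k_sd' must be positive")
  structure(list(material = stats$material,
                 tube_potential_kvp = tube_potential_kvp,
                 lower_hu = stats$mean_hu - k_sd * stats$sd_hu,
                 upper_hu = stats$mean_hu + k_sd * stats$sd_hu,
                 mean_hu = stats$mean_hu, sd_hu = stats$sd_hu,
                 k_sd = k_sd, source_series = stats$source_series),
            class = "threshold_pair")
}

#' @rdname compute_thresholds
#' @param lower_hu,upper_hu explicit bounds (`lower_hu <= upper_hu`).
#' @param material optional material id.
#' @export
threshold_pair <- function(lower_hu, upper_hu, material = NA_character_,
                           k_sd = NA_real_, tube_potential_kvp = NA) {
  if (!is_len(lower_hu, 1) || !is_len(upper_hu, 1) || lower_hu > upper_hu) {
    stopf("'lower_hu' must not exceed 'upper_hu'")
  }
  structure(list(material = material,
                 tube_potential_kvp = tube_potential_kvp,
                 lower_hu = lower_hu, upper_hu = upper_hu,
                 mean_hu = NA_real_, sd_hu = NA_real_, k_sd = k_sd,
                 source_series = NA_character_),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair> %s%s: [%.2f, %.2f] HU%s\n",
              x$material,
              if (is.na(x$tube_potential_kvp)) ""
              else sprintf(" @ %s kVp", x$tube_potential_kvp),
              x$lower_hu, x$upper_hu,
              if (is.na(x$k_sd)) "" else sprintf(" (mean +/- %g SD)", x$k_sd)))
  invisible(x)
}

#' Classify out-of-range voxels
#'
#' Marks every voxel whose CT number lies strictly below the lower or
#' strictly above the upper threshold. The interval is closed: values
#' exactly equal to a bound count as normal tissue.
#'
#' @param vol a [ct_volume()].
#' @param thr a `threshold_pair`.
#' @return a [ct_mask()] of artifact-classified voxels.
#' @export
classify_out_of_range <- function(vol, thr) {
  stopifnot(inherits(vol, "ct_volume"), inherits(thr, "threshold_pair"))
  ct_mask(vol$data < thr$lower_hu | vol$data > thr$upper_hu,
          spacing_mm = vol$spacing_mm, origin_mm = vol$origin_mm)
}

#' Erode a mask by a metric margin
#'
#' Retains the voxels whose Euclidean distance to the mask complement —
#' measured in millimetres with the grid's (possibly anisotropic) spacing —
#' strictly exceeds `margin_mm`. This is how partial-volume safety margins
#' stated in mm (e.g. 2 mm to neighbouring water and bone marrow, 3 cm to
#' the bath surface and container) are applied to reference and VOI masks.
#' Voxels beyond the grid boundary are not treated as complement, so a mask
#' face flush with the volume edge does not erode from that face.
#'
#' @param mask a [ct_mask()].
#' @param margin_mm margin (>= 0); 0 returns the mask unchanged. May return
#'   an empty mask if the margin exceeds the mask half-width.
#' @return eroded [ct_mask()].
#' @export
erode_mask_mm <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "ct_mask"))
  if (!is_len(margin_mm, 1) || margin_mm < 0) {
    stopf("'margin_mm' must be non-negative")
  }
  if (margin_mm == 0) return(mask)
  d2 <- edt_sq_cpp(as.logical(mask$data), dim(mask$data), mask$spacing_mm)
  keep <- array(d2 > margin_mm^2, dim(mask$data))
  ct_mask(mask$data & keep, spacing_mm = mask$spacing_mm,
          origin_mm = mask$origin_mm)
}

#' Propagate a VOI mask to another co-registered series
#'
#' All series of a study are acquired in the exact same position, so a
#' manually defined VOI is reused on every series by direct copy. Any grid
#' difference (shape, spacing or origin) is an error — there is no
#' resampling.
#'
#' @param voi a [ct_mask()].
#' @param target the [ct_volume()] (or `labeled_volume`) the mask is to be
#'   used with.
#' @return the same mask, bound to the target's grid.
#' @export
propagate_voi <- function(voi, target) {
  stopifnot(inherits(voi, "ct_mask"))
  if (inherits(target, "labeled_volume")) target <- target$image
  assert_same_grid(voi, target, "VOI and target series")
  ct_mask(voi$data, spacing_mm = target$spacing_mm,
          origin_mm = target$origin_mm)
}

#' Segment artifacts inside a volume of interest
#'
#' The artifact segmentation of a series is the intersection of the VOI with
#' all voxels whose CT numbers lie beyond the thresholds:
#' `classify_out_of_range(vol, thr) & voi`.
#'
#' @inheritParams classify_out_of_range
#' @param voi a [ct_mask()] on the same grid.
#' @return a [ct_mask()], subset of `voi`.
#' @export
segment_artifacts <- function(vol, thr, voi) {
  stopifnot(inherits(voi, "ct_mask"))
  assert_same_grid(vol, voi, "volume and VOI")
  out <- classify_out_of_range(vol, thr)
  out$data <- out$data & voi$data
  out
}
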