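#' Artifact percentage within a volume of interest
#'
#' `100 * |artifact ∩ voi| / |voi|`. The artifact mask is intersected with
#' the VOI before counting, so a mask that extends beyond the VOI is handled
#' consistently.
#'
#' @param artifact artifact [ct_mask()].
#' @param voi non-empty VOI [ct_mask()] on the same grid.
#' @return percentage in `[0, 100]`.
#' @export
artifact_fraction <- function(artifact, voi) {
  stopifnot(inherits(artifact, "ct_mask"), inherits(voi, "ct_mask"))
  assert_same_grid(artifact, voi, "artifact mask and VOI")
  nv <- sum(voi$data)
  if (nv == 0) stopf("VOI is empty")
  100 * sum(artifact$data & voi$data) / nv
}

#' Misclassification correction factor
#'
#' Applies the thresholds to an artifact-free reference segmentation and
#' measures the percentage of its voxels classified as artifacts. Under
#' mean +/- 3 SD thresholds and normally distributed CT numbers this is
#' about 0.3% (analytically 2 * pnorm(-3) = 0.27%), but it is computed per
#' series and per material because noise and reconstruction differences
#' move the actual rate. The factor is subtracted from raw artifact
#' percentages by [corrected_fraction()].
#'
#' @param vol the series' [ct_volume()].
#' @param reference non-empty artifact-free reference [ct_mask()].
#' @param thr a [threshold_pair()].
#' @return percentage in `[0, 100]`.
#' @export
correction_factor <- function(vol, reference, thr) {
  stopifnot(inherits(reference, "ct_mask"))
  if (!sum(reference$data)) stopf("reference mask is empty")
  artifact_fraction(classify_out_of_range(vol, thr), reference)
}

#' Correction-subtracted artifact percentage
#'
#' `max(raw - correction, 0)`: the correction factor is subtracted from the
#' raw percentage and the result floored at zero, since a negative artifact
#' volume is meaningless.
#'
#' @param raw,correction percentages in `[0, 100]` (vectorised).
#' @return corrected percentage(s).
#' @export
corrected_fraction <- function(raw, correction) {
  if (any(raw < 0 | raw > 100) || any(correction < 0 | correction > 100)) {
    stopf("percentages must lie in [0, 100]")
  }
  pmax(raw - correction, 0)
}

#' Image noise from a water-bath-only series
#'
#' Noise is defined as the sample standard deviation of the CT numbers in a
#' water-bath segmentation of the companion acquisition without the phantom,
#' so that no peripheral artifacts can distort the measurement.
#'
#' @param water_only_vol [ct_volume()] of the water-only series.
#' @param water_mask non-empty water [ct_mask()].
#' @return noise SD in HU (>= 0).
#' @export
image_noise <- function(water_only_vol, water_mask) {
  region_stats(water_only_vol, water_mask)$sd_hu
}

#' Contrast-to-noise ratio between a tissue and the water bath
#'
#' Contrast between the tissue and water mean CT numbers, normalised by a
#' noise term. The default `"pooled_sd"` method divides by the quadratic
#' mean of the two region SDs, `sqrt((SD_t^2 + SD_w^2) / 2)`, which is the
#' form that reproduces the published phantom CNR values from the published
#' region statistics; `"water_sd"` divides by the water SD alone.
#'
#' @param tissue,water `material_stats` for the tissue and the water bath
#'   (with phantom present).
#' @param method denominator choice, see Details.
#' @return CNR (dimensionless, >= 0).
#' @examples
#' cnr(material_stats(595.96, 125.94), material_stats(-0.03, 56.87))  # 6.10
#' @export
cnr <- function(tissue, water, method = c("pooled_sd", "water_sd")) {
  stopifnot(inherits(tissue, "material_stats"),
            inherits(water, "material_stats"))
  method <- match.arg(method)
  den <- switch(method,
                pooled_sd = sqrt((tissue$sd_hu^2 + water$sd_hu^2) / 2),
                water_sd = water$sd_hu)
  if (den <= 0) stopf("zero noise denominator: CNR undefined")
  abs(tissue$mean_hu - water$mean_hu) / den
}

#' Per-slice artifact percentage as a function of distance
#'
#' Computes the artifact percentage within the VOI slice by slice and keys
#' it by the axial distance `|z - reference| * spacing_z` in mm from a
#' reference slice (typically the slice of the prosthesis tip). Slices where
#' the VOI is empty are omitted. With streaks decaying away from the
#' prosthesis the profile shows the characteristic negative distance trend.
#'
#' @param artifact artifact [ct_mask()].
#' @param voi VOI [ct_mask()] spanning at least two slices.
#' @param reference_slice 1-based index of the reference slice.
#' @return data.frame with `slice`, `distance_mm`, `percent`.
#' @export
distance_profile <- function(artifact, voi, reference_slice) {
  stopifnot(inherits(artifact, "ct_mask"), inherits(voi, "ct_mask"))
  assert_same_grid(artifact, voi, "artifact mask and VOI")
  nz <- dim(voi$data)[3]
  if (!is_count(reference_slice) || reference_slice > nz) {
    stopf("'reference_slice' must be a slice index in 1..%d", nz)
  }
  nv <- apply(voi$data, 3, sum)
  keep <- which(nv > 0)
  if (length(keep) < 2) {
    stopf("VOI must span at least 2 slices (found %d)", length(keep))
  }
  na <- apply(artifact$data & voi$data, 3, sum)
  data.frame(slice = keep,
             distance_mm = abs(keep - reference_slice) * voi$spacing_mm[3],
             percent = 100 * na[keep] / nv[keep])
}
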