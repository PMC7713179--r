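#' Bundled reference HU statistics for the hip-prosthesis phantom protocols
#'
#' Published mean and standard deviation of CT numbers (HU) measured in the
#' artifact-free reference segmentations of a hip-prosthesis phantom study:
#' cortical bone, bone marrow, water bath with phantom, and a water-bath-only
#' companion acquisition, for twelve acquisition protocols on one scanner
#' (conventional energy-integrating detector, and photon-counting detector in
#' Macro and Chess mode reconstructed as high-energy threshold images at
#' 100/120/140 kVp with 55-75 keV thresholds). These values seed the
#' synthetic phantom simulator's material HU means and noise magnitudes and
#' are the inputs to the contrast-to-noise ratio computation.
#'
#' @return data.frame with one row per protocol: `series`, `detector`
#'   ("EID"/"PCD"), `mode` ("none"/"Macro"/"Chess"), `kvp`, `kev` (NA for
#'   EID), and per-region `mean`/`sd` columns in HU (`cortical_*`,
#'   `marrow_*`, `water_*` for the bath with phantom, `water_only_*` for the
#'   bath alone).
#' @examples
#' reference_series_stats()[, c("series", "cortical_mean", "water_only_sd")]
#' @export
reference_series_stats <- function() {
  data.frame(
    series = c("Macro-HTI 140/75", "Chess-HTI 140/75", "Chess-HTI 140/65",
               "EID-CT 140",
               "Macro-HTI 120/70", "Chess-HTI 120/70", "Chess-HTI 120/60",
               "EID-CT 120",
               "Macro-HTI 100/65", "Chess-HTI 100/65", "Chess-HTI 100/55",
               "EID-CT 100"),
    detector = rep(c("PCD", "PCD", "PCD", "EID"), 3),
    mode = rep(c("Macro", "Chess", "Chess", "none"), 3),
    kvp = rep(c(140L, 120L, 100L), each = 4),
    kev = c(75L, 75L, 65L, NA, 70L, 70L, 60L, NA, 65L, 65L, 55L, NA),
    cortical_mean = c(595.96, 614.68, 607.59, 679.70,
                      615.25, 640.22, 652.25, 711.29,
                      652.69, 671.94, 709.94, 761.15),
    cortical_sd = c(125.94, 123.64, 141.91, 80.93,
                    139.17, 124.91, 128.28, 84.67,
                    141.56, 142.05, 121.90, 86.63),
    marrow_mean = c(-647.91, -661.37, -632.69, -674.12,
                    -641.32, -665.98, -650.65, -676.49,
                    -645.39, -665.54, -667.90, -679.67),
    marrow_sd = c(112.03, 119.87, 117.38, 81.22,
                  111.60, 121.25, 115.25, 81.12,
                  104.58, 120.07, 104.16, 80.87),
    water_mean = c(-0.03, 0.38, 1.70, -0.34,
                   1.08, 0.73, 0.36, -0.36,
                   0.54, 0.09, -0.78, -0.29),
    water_sd = c(56.87, 80.12, 65.26, 34.62,
                 57.10, 79.89, 62.67, 34.60,
                 57.81, 80.84, 61.96, 35.57),
    water_only_mean = c(0.18, 0.02, 1.34, -0.27,
                        1.60, 0.26, -0.09, -0.12,
                        0.29, 0.17, -0.66, 0.35),
    water_only_sd = c(55.23, 77.25, 63.21, 32.95,
                      55.62, 76.92, 60.28, 32.80,
                      55.53, 77.37, 59.24, 33.64),
    stringsAsFactors = FALSE
  )
}

#' Build an acquisition protocol from the bundled reference statistics
#'
#' @param series one of the series names in [reference_series_stats()],
#'   e.g. `"EID-CT 140"` or `"Macro-HTI 140/75"`.
#' @param metal_hu HU assigned to the metal stem (titanium-like, clipped
#'   scanner output; exceeds every plausible threshold).
#' @return an [acquisition_protocol()].
#' @examples
#' reference_protocol("EID-CT 140")
#' @export
reference_protocol <- function(series, metal_hu = 3000) {
  tab <- reference_series_stats()
  i <- match(series, tab$series)
  if (is.na(i)) {
    stopf("unknown reference series '%s'; see reference_series_stats()",
          series)
  }
  r <- tab[i, ]
  acquisition_protocol(
    detector = r$detector,
    mode = r$mode,
    tube_potential_kvp = r$kvp,
    energy_threshold_kev = if (is.na(r$kev)) NULL else r$kev,
    material_means_hu = c(cortical_bone = r$cortical_mean,
                          bone_marrow = r$marrow_mean,
                          water = r$water_mean),
    material_sds_hu = c(cortical_bone = r$cortical_sd,
                        bone_marrow = r$marrow_sd,
                        water = r$water_sd),
    metal_hu = metal_hu,
    noise_sd_hu = r$water_only_sd,
    water_only_mean_hu = r$water_only_mean,
    id = r$series
  )
}
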