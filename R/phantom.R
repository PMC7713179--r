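#' Material label codes used by the synthetic phantom
#'
#' @return named integer vector: air 0, water 1, cortical_bone 2,
#'   bone_marrow 3, metal 4.
#' @export
material_codes <- function() {
  c(air = 0L, water = 1L, cortical_bone = 2L, bone_marrow = 3L, metal = 4L)
}

#' Geometry of the synthetic hip-prosthesis phantom
#'
#' Describes a water bath (default 22 cm wide, 13 cm high in plane) holding a
#' foam femur model — an elliptical cortical shell with a marrow core — into
#' which a tapered elliptical metal stem is embedded (proximal diameters
#' 5 x 4 cm narrowing to 3.2 x 3.6 cm at the distal tip). Along z the layout
#' is, from distal to proximal: an artifact-free reference slab (default
#' 7.2 cm), a separating gap (default 10 cm), then the prosthesis zone whose
#' distal end is the stem tip, overlapped by the volume-of-interest slab
#' (default 9 cm). A small air pad surrounds the bath in-plane.
#'
#' All lengths in mm. `femur_outer_radii_mm` are the outer semi-axes of the
#' cortical ellipse; `stem_*_axes_mm` are full diameters, matching how
#' prosthesis dimensions are quoted clinically.
#'
#' @param bath_width_mm,bath_height_mm in-plane bath extent.
#' @param femur_outer_radii_mm outer semi-axes (x, y) of the cortical shell.
#' @param cortical_thickness_mm shell thickness.
#' @param stem_proximal_axes_mm,stem_distal_axes_mm stem diameters (x, y) at
#'   the proximal end and the distal tip; interpolated linearly along z.
#' @param stem_length_mm stem extent along z.
#' @param voi_length_mm length of the volume-of-interest slab, starting at
#'   the stem tip.
#' @param reference_length_mm length of the artifact-free reference slab.
#' @param reference_gap_mm gap separating the reference slab from the
#'   prosthesis/VOI zone.
#' @param voxel_spacing_mm voxel spacing (x, y, z); the default 0.5 x 0.5 x 2
#'   pairs in-plane detail with a 2 mm reconstructed slice thickness.
#' @param air_pad_mm air border around the bath in-plane.
#' @return object of class `phantom_spec`.
#' @examples
#' phantom_spec()
#' @export
phantom_spec <- function(bath_width_mm = 220, bath_height_mm = 130,
                         femur_outer_radii_mm = c(38, 33),
                         cortical_thickness_mm = 6,
                         stem_proximal_axes_mm = c(50, 40),
                         stem_distal_axes_mm = c(32, 36),
                         stem_length_mm = 90,
                         voi_length_mm = 90,
                         reference_length_mm = 72,
                         reference_gap_mm = 100,
                         voxel_spacing_mm = c(0.5, 0.5, 2),
                         air_pad_mm = 5) {
  for (nm in c("bath_width_mm", "bath_height_mm", "cortical_thickness_mm",
               "stem_length_mm", "voi_length_mm", "reference_length_mm")) {
    v <- get(nm)
    if (!is_len(v, 1, min = 0)) stopf("'%s' must be a positive length", nm)
  }
  if (!is_len(reference_gap_mm, 1) || reference_gap_mm < 0) {
    stopf("'reference_gap_mm' must be non-negative")
  }
  if (!is_len(femur_outer_radii_mm, 2, min = 0) ||
      !is_len(stem_proximal_axes_mm, 2, min = 0) ||
      !is_len(stem_distal_axes_mm, 2, min = 0)) {
    stopf("radii/axes must be pairs of positive lengths")
  }
  if (!is_len(voxel_spacing_mm, 3, min = 0)) {
    stopf("'voxel_spacing_mm' must be 3 positive lengths")
  }
  marrow <- femur_outer_radii_mm - cortical_thickness_mm
  if (any(marrow <= 0)) {
    stopf("cortical shell thicker than the femur radii: no marrow cavity")
  }
  stem_semi <- pmax(stem_proximal_axes_mm, stem_distal_axes_mm) / 2
  if (any(stem_semi >= marrow)) {
    stopf(paste0("stem does not fit inside the marrow cavity ",
                 "(stem semi-axes %s mm vs marrow radii %s mm)"),
          paste(stem_semi, collapse = " x "),
          paste(marrow, collapse = " x "))
  }
  if (2 * femur_outer_radii_mm[1] >= bath_width_mm ||
      2 * femur_outer_radii_mm[2] >= bath_height_mm) {
    stopf("femur does not fit inside the water bath")
  }
  z_tip <- reference_length_mm + reference_gap_mm
  spec <- list(
    bath_width_mm = bath_width_mm, bath_height_mm = bath_height_mm,
    femur_outer_radii_mm = femur_outer_radii_mm,
    cortical_thickness_mm = cortical_thickness_mm,
    stem_proximal_axes_mm = stem_proximal_axes_mm,
    stem_distal_axes_mm = stem_distal_axes_mm,
    stem_length_mm = stem_length_mm,
    voi_length_mm = voi_length_mm,
    reference_length_mm = reference_length_mm,
    reference_gap_mm = reference_gap_mm,
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    air_pad_mm = air_pad_mm,
    z_tip_mm = z_tip,
    z_total_mm = z_tip + max(stem_length_mm, voi_length_mm)
  )
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_spec> bath %g x %g mm, femur %g x %g mm (shell %g mm),\n",
    "  stem %gx%g -> %gx%g mm over %g mm, VOI %g mm, reference %g mm",
    " (gap %g mm)\n  spacing %s mm, z extent %g mm\n"),
    x$bath_width_mm, x$bath_height_mm,
    2 * x$femur_outer_radii_mm[1], 2 * x$femur_outer_radii_mm[2],
    x$cortical_thickness_mm,
    x$stem_proximal_axes_mm[1], x$stem_proximal_axes_mm[2],
    x$stem_distal_axes_mm[1], x$stem_distal_axes_mm[2],
    x$stem_length_mm, x$voi_length_mm, x$reference_length_mm,
    x$reference_gap_mm,
    paste(format(x$voxel_spacing_mm), collapse = " x "), x$z_total_mm))
  invisible(x)
}

#' Acquisition protocol for the synthetic phantom
#'
#' Bundles the detector type, acquisition mode, tube potential and (for the
#' photon-counting detector) the energy threshold of the reconstructed
#' high-energy threshold image, together with the material HU means/SDs that
#' the simulated volume should reproduce and the global image-noise SD.
#'
#' @param detector `"EID"` (energy-integrating) or `"PCD"` (photon-counting).
#' @param mode `"Macro"` or `"Chess"` for PCD; `"none"` for EID.
#' @param tube_potential_kvp tube potential, one of 100, 120, 140.
#' @param energy_threshold_kev PCD energy threshold (keV); must be absent for
#'   EID and present for PCD.
#' @param material_means_hu,material_sds_hu named numeric vectors covering
#'   `cortical_bone`, `bone_marrow` and `water`.
#' @param metal_hu HU of the metal stem (default 3000, a clipped
#'   titanium-like value that exceeds every threshold).
#' @param noise_sd_hu global Gaussian image-noise SD; when `NULL` for a Chess
#'   protocol, [simulate_acquisition_set()] derives it as sqrt(2) times the
#'   matching Macro protocol's SD (half the detector subpixels per threshold
#'   setting).
#' @param water_only_mean_hu mean HU of the companion water-bath-only series.
#' @param id series identifier.
#' @return object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(detector = c("EID", "PCD"),
                                 mode = c("none", "Macro", "Chess"),
                                 tube_potential_kvp,
                                 energy_threshold_kev = NULL,
                                 material_means_hu,
                                 material_sds_hu = NULL,
                                 metal_hu = 3000,
                                 noise_sd_hu = NULL,
                                 water_only_mean_hu = 0,
                                 id = NULL) {
  detector <- match.arg(detector)
  mode <- match.arg(mode)
  if (!tube_potential_kvp %in% c(100, 120, 140)) {
    stopf("'tube_potential_kvp' must be 100, 120 or 140")
  }
  if (detector == "PCD") {
    if (mode == "none") stopf("PCD protocols require an acquisition mode")
    if (is.null(energy_threshold_kev)) {
      stopf("PCD protocols require an energy threshold (keV)")
    }
  } else {
    if (mode != "none" || !is.null(energy_threshold_kev)) {
      stopf("EID protocols have neither acquisition mode nor energy threshold")
    }
  }
  need <- c("cortical_bone", "bone_marrow", "water")
  if (!all(need %in% names(material_means_hu))) {
    stopf("material_means_hu must cover %s", paste(need, collapse = ", "))
  }
  if (!is.null(material_sds_hu) && !all(need %in% names(material_sds_hu))) {
    stopf("material_sds_hu must cover %s", paste(need, collapse = ", "))
  }
  if (is.null(id)) {
    id <- if (detector == "EID") {
      sprintf("EID-CT %d", tube_potential_kvp)
    } else {
      sprintf("%s-HTI %d/%d", mode, tube_potential_kvp, energy_threshold_kev)
    }
  }
  structure(list(id = id, detector = detector, mode = mode,
                 tube_potential_kvp = tube_potential_kvp,
                 energy_threshold_kev = energy_threshold_kev,
                 material_means_hu = material_means_hu[need],
                 material_sds_hu = if (is.null(material_sds_hu)) NULL
                                   else material_sds_hu[need],
                 metal_hu = metal_hu,
                 noise_sd_hu = noise_sd_hu,
                 water_only_mean_hu = water_only_mean_hu),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> %s (%s%s, %d kVp%s), noise SD %s HU\n",
              x$id, x$detector,
              if (x$mode == "none") "" else paste0(" ", x$mode),
              x$tube_potential_kvp,
              if (is.null(x$energy_threshold_kev)) ""
              else sprintf("/%d keV", x$energy_threshold_kev),
              if (is.null(x$noise_sd_hu)) "unset"
              else format(x$noise_sd_hu)))
  invisible(x)
}

# In-plane and axial geometry shared by build_phantom()/build_water_bath().
# Coordinates are voxel centres; (0,0) is the bath centre in-plane, z runs
# from 0 at the distal (reference) end.
phantom_geometry <- function(spec) {
  sp <- spec$voxel_spacing_mm
  nx <- ceiling((spec$bath_width_mm + 2 * spec$air_pad_mm) / sp[1])
  ny <- ceiling((spec$bath_height_mm + 2 * spec$air_pad_mm) / sp[2])
  nz <- ceiling(spec$z_total_mm / sp[3])
  x <- (seq_len(nx) - (nx + 1) / 2) * sp[1]
  y <- (seq_len(ny) - (ny + 1) / 2) * sp[2]
  z <- (seq_len(nz) - 0.5) * sp[3]
  xg <- matrix(x, nx, ny)
  yg <- matrix(y, nx, ny, byrow = TRUE)
  bath2d <- abs(xg) <= spec$bath_width_mm / 2 &
            abs(yg) <= spec$bath_height_mm / 2
  a_o <- spec$femur_outer_radii_mm[1]
  b_o <- spec$femur_outer_radii_mm[2]
  a_i <- a_o - spec$cortical_thickness_mm
  b_i <- b_o - spec$cortical_thickness_mm
  outer2d <- (xg / a_o)^2 + (yg / b_o)^2 <= 1
  marrow2d <- (xg / a_i)^2 + (yg / b_i)^2 <= 1
  stem_slices <- which(z >= spec$z_tip_mm &
                       z <= spec$z_tip_mm + spec$stem_length_mm)
  voi_slices <- which(z >= spec$z_tip_mm &
                      z <= spec$z_tip_mm + spec$voi_length_mm)
  ref_slices <- which(z <= spec$reference_length_mm)
  # stem semi-axes at height z: linear taper from distal tip to proximal end
  stem_semi_at <- function(zv) {
    t <- pmin(pmax((zv - spec$z_tip_mm) / spec$stem_length_mm, 0), 1)
    list(a = (spec$stem_distal_axes_mm[1] +
                t * (spec$stem_proximal_axes_mm[1] -
                     spec$stem_distal_axes_mm[1])) / 2,
         b = (spec$stem_distal_axes_mm[2] +
                t * (spec$stem_proximal_axes_mm[2] -
                     spec$stem_distal_axes_mm[2])) / 2)
  }
  list(dim = c(nx, ny, nz), spacing = sp, x = x, y = y, z = z,
       xg = xg, yg = yg, bath2d = bath2d, outer2d = outer2d,
       marrow2d = marrow2d, stem_slices = stem_slices,
       voi_slices = voi_slices, ref_slices = ref_slices,
       stem_semi_at = stem_semi_at)
}

#' Build a noiseless, artifact-free synthetic phantom volume
#'
#' Rasterises the phantom geometry onto the voxel grid and assigns each
#' voxel the HU mean of its material under the given protocol (air is
#' -1000 HU, metal `protocol$metal_hu`). The result is the clean starting
#' point for [inject_artifacts()] and [add_noise()].
#'
#' @param spec a [phantom_spec()].
#' @param protocol an [acquisition_protocol()].
#' @return object of class `labeled_volume`: list with `image`
#'   ([ct_volume()]), `labels` (integer array of [material_codes()]),
#'   `artifact_truth` (logical array, all `FALSE` here), plus `spec`,
#'   `protocol` and `seed` bookkeeping.
#' @examples
#' vol <- build_phantom(phantom_spec(voxel_spacing_mm = c(2, 2, 4)),
#'                      reference_protocol("EID-CT 140"))
#' table(vol$labels)
#' @export
build_phantom <- function(spec, protocol) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(protocol, "acquisition_protocol"))
  g <- phantom_geometry(spec)
  codes <- material_codes()
  base2d <- matrix(codes[["air"]], g$dim[1], g$dim[2])
  base2d[g$bath2d] <- codes[["water"]]
  base2d[g$outer2d] <- codes[["cortical_bone"]]
  base2d[g$marrow2d] <- codes[["bone_marrow"]]
  labels <- array(base2d, g$dim)
  for (k in g$stem_slices) {
    s <- g$stem_semi_at(g$z[k])
    stem2d <- (g$xg / s$a)^2 + (g$yg / s$b)^2 <= 1
    sl <- labels[, , k]
    sl[stem2d] <- codes[["metal"]]
    labels[, , k] <- sl
  }
  hu <- c(-1000,
          protocol$material_means_hu[["water"]],
          protocol$material_means_hu[["cortical_bone"]],
          protocol$material_means_hu[["bone_marrow"]],
          protocol$metal_hu)
  image <- array(hu[labels + 1L], g$dim)
  structure(list(
    image = ct_volume(image, spacing_mm = g$spacing),
    labels = labels,
    artifact_truth = array(FALSE, g$dim),
    spec = spec, protocol = protocol, seed = NA_integer_
  ), class = "labeled_volume")
}

#' Build the companion water-bath-only volume
#'
#' Same grid and bath as [build_phantom()] but without the femur model:
#' water everywhere inside the bath at the protocol's water-only mean HU.
#' Used for the noise measurement.
#'
#' @inheritParams build_phantom
#' @return a `labeled_volume` whose labels contain only air and water.
#' @export
build_water_bath <- function(spec, protocol) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(protocol, "acquisition_protocol"))
  g <- phantom_geometry(spec)
  codes <- material_codes()
  base2d <- matrix(codes[["air"]], g$dim[1], g$dim[2])
  base2d[g$bath2d] <- codes[["water"]]
  labels <- array(base2d, g$dim)
  image <- array(ifelse(labels == codes[["water"]],
                        protocol$water_only_mean_hu, -1000), g$dim)
  structure(list(
    image = ct_volume(image, spacing_mm = g$spacing),
    labels = labels,
    artifact_truth = array(FALSE, g$dim),
    spec = spec, protocol = protocol, seed = NA_integer_
  ), class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  codes <- material_codes()
  counts <- vapply(codes, function(v) sum(x$labels == v), numeric(1))
  cat(sprintf("<labeled_volume> %s (%s), %d x %d x %d voxels\n",
              x$protocol$id, x$protocol$detector, d[1], d[2], d[3]))
  cat("  voxels: ", paste(sprintf("%s %d", names(counts), counts),
                          collapse = ", "), "\n", sep = "")
  cat(sprintf("  artifact truth: %d voxels\n", sum(x$artifact_truth)))
  invisible(x)
}

#' Extract a material or slab mask from a labeled volume
#'
#' @param vol a `labeled_volume`.
#' @param material material name (see [material_codes()]).
#' @return a [ct_mask()] on the volume's grid.
#' @export
material_mask <- function(vol, material) {
  codes <- material_codes()
  if (!material %in% names(codes)) stopf("unknown material '%s'", material)
  ct_mask(vol$labels == codes[[material]],
          spacing_mm = vol$image$spacing_mm,
          origin_mm = vol$image$origin_mm)
}

# logical z-slab mask from slice indices
slab_mask <- function(vol, slices) {
  d <- dim(vol$labels)
  m <- array(FALSE, d)
  m[, , slices] <- TRUE
  ct_mask(m, spacing_mm = vol$image$spacing_mm,
          origin_mm = vol$image$origin_mm)
}

#' @describeIn material_mask mask of the artifact-free reference slab
#'   (distal z section).
#' @export
reference_slab_mask <- function(vol) {
  slab_mask(vol, phantom_geometry(vol$spec)$ref_slices)
}

#' @describeIn material_mask mask of the volume-of-interest slab containing
#'   the prosthesis.
#' @export
voi_slab_mask <- function(vol) {
  slab_mask(vol, phantom_geometry(vol$spec)$voi_slices)
}

#' @describeIn material_mask mask of the bath interior (water or submerged
#'   femur), used for container-margin handling.
#' @export
bath_mask <- function(vol) {
  g <- phantom_geometry(vol$spec)
  ct_mask(array(g$bath2d, g$dim), spacing_mm = vol$image$spacing_mm,
          origin_mm = vol$image$origin_mm)
}
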