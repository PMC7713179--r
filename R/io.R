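#' Read and write CT volumes and masks as NIfTI
#'
#' Volumes are stored as signed 16-bit NIfTI (HU values are rounded to the
#' nearest integer on write, which is lossless for CT data), masks as
#' unsigned 8-bit. Voxel spacing travels in the NIfTI header; orientation is
#' written as the identity, so the origin of a read volume is always
#' `c(0, 0, 0)`.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` a [ct_volume()]; `read_mask()` a [ct_mask()];
#'   the writers return `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' v <- ct_volume(array(round(rnorm(60, 0, 30)), c(5, 4, 3)), c(1, 1, 2))
#' write_volume(v, f)
#' w <- read_volume(f)
#' all.equal(v$data, w$data)
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stopf("expected a 3D volume, '%s' has %d dimension(s)", path, length(d))
  }
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stopf("malformed header in '%s': invalid voxel spacing", path)
  }
  ct_volume(array(as.numeric(img), d), spacing_mm = sp[1:3])
}

#' @rdname read_volume
#' @param vol a [ct_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(round(vol$data))
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  if (!all(vol$data %in% c(0, 1))) {
    stopf("'%s' is not a binary mask (values other than 0/1 present)", path)
  }
  ct_mask(vol$data != 0, spacing_mm = vol$spacing_mm,
          origin_mm = vol$origin_mm)
}

#' @rdname read_volume
#' @param mask a [ct_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ct_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write an integer label map as NIfTI
#'
#' @param labels integer 3D array of material codes (see [material_codes()]).
#' @param spacing_mm voxel spacing.
#' @param path output path.
#' @keywords internal
#' @export
write_labels <- function(labels, spacing_mm, path) {
  img <- RNifti::asNifti(labels)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Load a study configuration from YAML
#'
#' Reads a YAML description of an artifact-quantification study (series list,
#' materials, margins, threshold multiplier, optional simulation parameters)
#' and validates it into a [study_config()] object, filling defaults:
#' `k_sd = 3`, margins of 2 mm for cortical bone and bone marrow and 30 mm
#' for water.
#'
#' @param path YAML file path.
#' @return a validated [study_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(cfg$series)) {
    stopf("config must contain a 'series' list")
  }
  spec <- if (!is.null(cfg$phantom)) do.call(phantom_spec, cfg$phantom)
          else phantom_spec()
  margins <- c(cortical_bone = 2, bone_marrow = 2, water = 30)
  if (!is.null(cfg$margins_mm)) {
    m <- unlist(cfg$margins_mm)
    unknown <- setdiff(names(m), names(margins))
    if (length(unknown)) stopf("unknown material in margins_mm: %s",
                               paste(unknown, collapse = ", "))
    margins[names(m)] <- m
  }
  study_config(
    series = cfg$series,
    spec = spec,
    k_sd = cfg$k_sd %||% 3,
    margins_mm = margins,
    materials = cfg$materials %||% c("cortical_bone", "bone_marrow", "water"),
    artifact = cfg$artifact %||% list(),
    simulate = cfg$simulate %||% FALSE,
    seed = cfg$seed %||% 1L
  )
}
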