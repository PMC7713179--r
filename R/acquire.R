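#' Simulate a co-registered set of phantom and water-only acquisitions
#'
#' Generates, on one shared voxel grid, a phantom series (with streak
#' artifacts and noise) and a matching water-bath-only companion series for
#' each protocol — the in-silico analogue of scanning the phantom and the
#' bare bath in the exact same position, which is what makes VOI propagation
#' across series valid.
#'
#' Noise handling: each protocol's `noise_sd_hu` is used for both its
#' phantom and water-only series; a Chess protocol without a configured SD
#' inherits sqrt(2) times the SD of the Macro protocol at the same tube
#' potential in the set (half the detector subpixels per threshold setting).
#' The ground-truth cutoff defaults to `3 *` the noise SD of the EID
#' protocol at the same tube potential (the threshold-source series), i.e.
#' the classification half-width of the downstream mean +/- 3 SD rule, so
#' that measured artifact percentages are comparable to the injected truth.
#'
#' Per-series noise and streak seeds are fanned out deterministically from
#' `seed` and the series id, so identical inputs give bitwise-identical
#' output and adding a series does not change the others.
#'
#' @param spec a [phantom_spec()].
#' @param protocols list of [acquisition_protocol()] objects or series-name
#'   strings resolved through [reference_protocol()].
#' @param artifact list of streak parameters: `n_streaks`, `decay_mm`,
#'   `axial_decay_mm`, `sharpness`, `truth_cutoff_hu` (default 3 x
#'   threshold-source noise SD) and either `amplitude_hu` or
#'   `target_percent` — a requested ground-truth artifact percentage in
#'   bone marrow within the VOI, met by fixing the amplitude at 10x the
#'   cutoff and solving the ray sharpness with
#'   [calibrate_streak_sharpness()]. An empty list (or `amplitude_hu = 0`)
#'   injects nothing.
#' @param seed master integer seed.
#' @return object of class `acquisition_set`: list with `spec`, `seed` and
#'   `series`, a named list whose elements carry `protocol`, `phantom` and
#'   `water_only` `labeled_volume`s, the applied `sigma_hu`, `amplitude_hu`
#'   and `truth_cutoff_hu`.
#' @examples
#' set <- simulate_acquisition_set(
#'   phantom_spec(voxel_spacing_mm = c(2, 2, 4)),
#'   protocols = list("EID-CT 140"),
#'   artifact = list(target_percent = 10), seed = 7)
#' names(set$series)
#' @export
simulate_acquisition_set <- function(spec, protocols,
                                     artifact = list(), seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!length(protocols)) stopf("at least one protocol is required")
  protocols <- lapply(protocols, function(p) {
    if (is.character(p)) reference_protocol(p) else p
  })
  ok <- vapply(protocols, inherits, logical(1), "acquisition_protocol")
  if (!all(ok)) stopf("'protocols' must be acquisition_protocol objects")
  ids <- vapply(protocols, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("duplicate series ids: %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  names(protocols) <- ids

  sigma_of <- function(p) {
    if (!is.null(p$noise_sd_hu)) return(p$noise_sd_hu)
    if (p$detector == "PCD" && p$mode == "Chess") {
      for (q in protocols) {
        if (q$detector == "PCD" && q$mode == "Macro" &&
            q$tube_potential_kvp == p$tube_potential_kvp &&
            !is.null(q$noise_sd_hu)) {
          return(sqrt(2) * q$noise_sd_hu)
        }
      }
    }
    stopf("no noise SD for series '%s' and no same-kVp Macro to derive it",
          p$id)
  }
  # classification half-width of the series whose reference region will
  # supply the thresholds: EID at the same kVp if present, else itself
  cutoff_sigma_of <- function(p) {
    for (q in protocols) {
      if (q$detector == "EID" &&
          q$tube_potential_kvp == p$tube_potential_kvp) {
        return(sigma_of(q))
      }
    }
    sigma_of(p)
  }

  art <- utils::modifyList(
    list(n_streaks = 16, decay_mm = 20, axial_decay_mm = 60,
         sharpness = 1, truth_cutoff_hu = NULL, amplitude_hu = NULL,
         target_percent = NULL),
    artifact)

  series <- vector("list", length(protocols))
  names(series) <- ids
  ref_grid <- NULL
  for (id in ids) {
    p <- protocols[[id]]
    sigma <- sigma_of(p)
    clean <- build_phantom(spec, p)
    if (is.null(ref_grid)) {
      ref_grid <- clean$image
    } else {
      assert_same_grid(ref_grid, clean$image, "series grids")
    }
    cutoff <- art$truth_cutoff_hu %||% (3 * cutoff_sigma_of(p))
    streak_seed <- sub_seed(seed, "streaks")  # shared: co-registered streaks
    tp <- art$target_percent %||% 0
    sharp <- art$sharpness
    amp <- art$amplitude_hu
    if (tp > 0) {
      # amplitude well clear of the cutoff; ray sharpness carries the target
      amp <- amp %||% (10 * cutoff)
      voi <- voi_slab_mask(clean)
      marrow <- material_mask(clean, "bone_marrow")
      marrow$data <- marrow$data & voi$data
      sharp <- calibrate_streak_sharpness(clean, marrow, tp,
                                          amplitude_hu = amp,
                                          n_streaks = art$n_streaks,
                                          decay_mm = art$decay_mm,
                                          axial_decay_mm = art$axial_decay_mm,
                                          truth_cutoff_hu = cutoff,
                                          seed = streak_seed)
    } else if (is.null(amp)) {
      amp <- 0
    }
    phantom <- inject_artifacts(clean, amplitude_hu = amp,
                                n_streaks = art$n_streaks,
                                decay_mm = art$decay_mm,
                                axial_decay_mm = art$axial_decay_mm,
                                sharpness = sharp,
                                truth_cutoff_hu = cutoff,
                                seed = streak_seed)
    phantom <- add_noise(phantom, sigma, seed = sub_seed(seed,
                                                         paste0(id, "/p")))
    water <- add_noise(build_water_bath(spec, p), sigma,
                       seed = sub_seed(seed, paste0(id, "/w")))
    series[[id]] <- list(protocol = p, phantom = phantom,
                         water_only = water, sigma_hu = sigma,
                         amplitude_hu = amp, sharpness = sharp,
                         truth_cutoff_hu = cutoff)
  }
  structure(list(spec = spec, seed = as.integer(seed), series = series),
            class = "acquisition_set")
}

#' @export
print.acquisition_set <- function(x, ...) {
  cat(sprintf("<acquisition_set> %d series on a %s-voxel grid (seed %d)\n",
              length(x$series),
              paste(dim(x$series[[1]]$phantom$labels), collapse = " x "),
              x$seed))
  for (s in x$series) {
    cat(sprintf("  %-18s sigma %6.2f HU, streak amplitude %7.1f HU\n",
                s$protocol$id, s$sigma_hu, s$amplitude_hu))
  }
  invisible(x)
}

#' Write an acquisition set to disk as NIfTI
#'
#' Writes, per series, the phantom image, the water-only image, the label
#' map and the ground-truth artifact mask, plus shared reference/VOI slab
#' masks, into `dir`. File names are derived from sanitised series ids.
#'
#' @param set an `acquisition_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, a data.frame listing the files written.
#' @export
write_acquisition_set <- function(set, dir) {
  stopifnot(inherits(set, "acquisition_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in names(set$series)) {
    s <- set$series[[id]]
    tag <- gsub("[^A-Za-z0-9]+", "_", id)
    fp <- file.path(dir, paste0(tag, "_phantom.nii.gz"))
    fw <- file.path(dir, paste0(tag, "_water_only.nii.gz"))
    fl <- file.path(dir, paste0(tag, "_labels.nii.gz"))
    ft <- file.path(dir, paste0(tag, "_artifact_truth.nii.gz"))
    write_volume(s$phantom$image, fp)
    write_volume(s$water_only$image, fw)
    write_labels(s$phantom$labels, s$phantom$image$spacing_mm, fl)
    write_mask(ct_mask(s$phantom$artifact_truth,
                       s$phantom$image$spacing_mm), ft)
    rows[[id]] <- data.frame(series = id, phantom = fp, water_only = fw,
                             labels = fl, truth = ft,
                             stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, rows))
}
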