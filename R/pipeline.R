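#' Study configuration
#'
#' Describes a complete artifact-quantification study: the series to
#' analyse, which series supplies the thresholds for each tube potential,
#' the materials and their partial-volume margins, the threshold multiplier
#' `k_sd`, and (for simulated studies) the phantom geometry and streak
#' parameters.
#'
#' Each element of `series` is a list with either a `protocol` entry (an
#' [acquisition_protocol()] or a series name resolved through
#' [reference_protocol()]) for simulated studies, or `id`, `detector`,
#' `kvp` plus `phantom`/`water_only` NIfTI paths for file-based studies.
#' An optional `threshold_source` names the series whose reference region
#' supplies this series' thresholds (`"self"` for self-derived); by default
#' a photon-counting series uses the conventional EID series at the same
#' tube potential, which must therefore exist.
#'
#' @param series list of series entries (see Details).
#' @param spec [phantom_spec()] used when `simulate = TRUE`.
#' @param k_sd threshold multiplier (default 3).
#' @param margins_mm named numeric: erosion margin per material applied to
#'   simulator-derived reference and VOI masks (defaults: 2 mm for
#'   cortical_bone and bone_marrow, 30 mm for water). File-based masks are
#'   used as provided.
#' @param materials materials to quantify.
#' @param artifact streak parameters passed to [simulate_acquisition_set()].
#' @param simulate logical: generate the series with the phantom simulator.
#' @param seed master seed.
#' @param reference_masks,voi_masks,water_only_masks named lists of NIfTI
#'   mask paths (file-based studies): per-material reference and VOI masks,
#'   and per-series water masks for the noise measurement.
#' @return object of class `study_config`.
#' @export
study_config <- function(series, spec = phantom_spec(), k_sd = 3,
                         margins_mm = c(cortical_bone = 2, bone_marrow = 2,
                                        water = 30),
                         materials = c("cortical_bone", "bone_marrow",
                                       "water"),
                         artifact = list(), simulate = TRUE, seed = 1,
                         reference_masks = NULL, voi_masks = NULL,
                         water_only_masks = NULL) {
  if (!length(series)) stopf("at least one series is required")
  if (!is_len(k_sd, 1, min = 0)) stopf("'k_sd' must be positive")
  known <- setdiff(names(material_codes()), c("air", "metal"))
  bad <- setdiff(materials, known)
  if (length(bad)) stopf("unknown material(s): %s", paste(bad, collapse = ", "))
  series <- lapply(series, function(s) {
    if (is.character(s)) s <- list(protocol = s)
    if (!is.null(s$protocol)) {
      if (is.character(s$protocol)) s$protocol <- reference_protocol(s$protocol)
      s$id <- s$id %||% s$protocol$id
      s$detector <- s$protocol$detector
      s$kvp <- s$protocol$tube_potential_kvp
    }
    if (is.null(s$id) || is.null(s$detector) || is.null(s$kvp)) {
      stopf("each series needs an id, detector and kvp (or a protocol)")
    }
    s
  })
  ids <- vapply(series, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stopf("series ids must be unique; duplicated: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(series) <- ids
  # every PCD series must have a designated threshold source
  for (s in series) {
    src <- s$threshold_source %||% NA_character_
    if (!is.na(src) && src != "self" && !src %in% ids) {
      stopf("series '%s': threshold_source '%s' is not a configured series",
            s$id, src)
    }
    if (is.na(src) && s$detector == "PCD") {
      eid <- vapply(series, function(q)
        q$detector == "EID" && q$kvp == s$kvp, logical(1))
      if (!any(eid)) {
        stopf(paste0("series '%s' (PCD, %d kVp) has no EID series at the ",
                     "same tube potential to derive thresholds from; add ",
                     "one or set threshold_source"), s$id, s$kvp)
      }
    }
  }
  structure(list(series = series, spec = spec, k_sd = k_sd,
                 margins_mm = margins_mm, materials = materials,
                 artifact = artifact, simulate = isTRUE(simulate),
                 seed = as.integer(seed),
                 reference_masks = reference_masks, voi_masks = voi_masks,
                 water_only_masks = water_only_masks),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d series, materials %s, k_sd %g, %s\n",
              length(x$series), paste(x$materials, collapse = "/"),
              x$k_sd,
              if (x$simulate) sprintf("simulated (seed %d)", x$seed)
              else "file-based"))
  invisible(x)
}

# threshold source id for a series within a config
resolve_threshold_source <- function(config, id) {
  s <- config$series[[id]]
  src <- s$threshold_source %||% NA_character_
  if (!is.na(src)) return(if (src == "self") id else src)
  if (s$detector == "EID") return(id)
  eid <- names(which(vapply(config$series, function(q)
    q$detector == "EID" && q$kvp == s$kvp, logical(1))))
  eid[1]
}

# Simulator-derived analysis masks: per material, the label mask eroded by
# its margin, split into the reference slab and the VOI slab.
analysis_masks <- function(vol, materials, margins_mm) {
  g <- phantom_geometry(vol$spec)
  ref_slab <- reference_slab_mask(vol)
  voi_slab <- voi_slab_mask(vol)
  ref <- list(); voi <- list()
  for (m in materials) {
    margin <- if (m %in% names(margins_mm)) margins_mm[[m]] else 0
    er <- erode_mask_mm(material_mask(vol, m), margin)
    rm_ <- er; rm_$data <- er$data & ref_slab$data
    vm <- er; vm$data <- er$data & voi_slab$data
    if (!sum(rm_$data)) {
      stopf("reference mask for '%s' is empty after %g mm margin", m, margin)
    }
    if (!sum(vm$data)) {
      stopf("VOI mask for '%s' is empty after %g mm margin", m, margin)
    }
    ref[[m]] <- rm_; voi[[m]] <- vm
  }
  list(reference = ref, voi = voi, tip_slice = g$voi_slices[1])
}

# Quantify one series against fixed thresholds and masks; shared by the
# simulated and file-based paths so re-running on saved inputs is exact.
quantify_series <- function(id, image, thresholds, ref_masks, voi_masks,
                            truth = NULL, tip_slice = NULL) {
  rows <- list(); profiles <- list()
  for (m in names(thresholds)) {
    thr <- thresholds[[m]]
    voi <- voi_masks[[m]]
    art <- segment_artifacts(image, thr, voi)
    nv <- sum(voi$data)
    na_ <- sum(art$data)
    raw <- 100 * na_ / nv
    corr <- correction_factor(image, ref_masks[[m]], thr)
    truth_pct <- if (is.null(truth)) NA_real_ else
      100 * sum(truth & voi$data) / nv
    rows[[m]] <- data.frame(
      series = id, material = m, voi_voxels = nv, artifact_voxels = na_,
      raw_percent = raw, correction_percent = corr,
      corrected_percent = corrected_fraction(raw, corr),
      truth_percent = truth_pct, stringsAsFactors = FALSE)
    if (!is.null(tip_slice)) {
      prof <- distance_profile(art, voi, tip_slice)
      prof <- cbind(series = id, material = m, prof,
                    stringsAsFactors = FALSE)
      profiles[[m]] <- prof
    }
  }
  list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
       profiles = profiles)
}

#' Run a complete artifact-quantification study
#'
#' Executes the full pipeline in order: obtain the series (simulated by the
#' phantom generator, or loaded from NIfTI files), compute reference
#' statistics on each threshold-source series, derive mean +/- k SD
#' thresholds per material and tube potential, propagate the VOI masks to
#' every series, segment out-of-range voxels inside each VOI, compute the
#' per-series/per-material correction factor on the artifact-free reference
#' region, and assemble artifact percentages (raw and corrected), image
#' noise, contrast-to-noise ratios and per-slice distance profiles.
#' Deterministic given the config seed.
#'
#' @param config a [study_config()] or the path to a YAML config file (see
#'   [load_config()]).
#' @return object of class `artifact_study`: list with data.frames
#'   `results`, `thresholds`, `noise`, `cnr`, a `profiles` data.frame, the
#'   `config`, and `provenance` (seed, package version). For simulated
#'   studies `results$truth_percent` carries the injected ground truth.
#' @examples
#' \donttest{
#' cfg <- study_config(series = list("EID-CT 140"),
#'                     spec = phantom_spec(voxel_spacing_mm = c(2, 2, 4)),
#'                     margins_mm = c(cortical_bone = 2, bone_marrow = 2,
#'                                    water = 6),
#'                     artifact = list(target_percent = 10), seed = 42)
#' fit <- run_study(cfg)
#' fit
#' }
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "study_config"))
  ids <- names(config$series)

  if (config$simulate) {
    protocols <- lapply(config$series, function(s) {
      if (is.null(s$protocol)) {
        stopf("series '%s' has no protocol; required when simulating", s$id)
      }
      s$protocol
    })
    set <- simulate_acquisition_set(config$spec, protocols,
                                    artifact = config$artifact,
                                    seed = config$seed)
    first <- set$series[[1]]$phantom
    masks <- analysis_masks(first, config$materials, config$margins_mm)
    get_image <- function(id) set$series[[id]]$phantom$image
    get_truth <- function(id) set$series[[id]]$phantom$artifact_truth
    get_noise_input <- function(id) {
      w <- set$series[[id]]$water_only
      wm <- erode_mask_mm(material_mask(w, "water"),
                          config$margins_mm[["water"]] %||% 0)
      list(vol = w$image, mask = wm)
    }
  } else {
    if (is.null(config$reference_masks) || is.null(config$voi_masks)) {
      stopf("file-based studies need reference_masks and voi_masks paths")
    }
    volumes <- lapply(config$series, function(s) {
      if (is.null(s$phantom)) stopf("series '%s' has no phantom path", s$id)
      read_volume(s$phantom)
    })
    ref <- lapply(config$reference_masks, read_mask)
    voi <- lapply(config$voi_masks, read_mask)
    for (m in names(voi)) voi[[m]] <- propagate_voi(voi[[m]], volumes[[1]])
    masks <- list(reference = ref, voi = voi, tip_slice = NULL)
    get_image <- function(id) volumes[[id]]
    get_truth <- function(id) NULL
    get_noise_input <- function(id) {
      s <- config$series[[id]]
      if (is.null(s$water_only) || is.null(config$water_only_masks[[id]])) {
        return(NULL)
      }
      list(vol = read_volume(s$water_only),
           mask = read_mask(config$water_only_masks[[id]]))
    }
  }

  # reference stats and thresholds, cached per threshold-source series
  stats_cache <- list()
  source_stats <- function(src) {
    if (is.null(stats_cache[[src]])) {
      img <- get_image(src)
      st <- lapply(config$materials, function(m)
        region_stats(img, masks$reference[[m]], material = m,
                     source_series = src))
      names(st) <- config$materials
      stats_cache[[src]] <<- st
    }
    stats_cache[[src]]
  }

  results <- list(); thr_rows <- list(); noise_rows <- list()
  cnr_rows <- list(); prof_rows <- list()
  for (id in ids) {
    src <- resolve_threshold_source(config, id)
    st <- source_stats(src)
    kvp <- config$series[[id]]$kvp
    thresholds <- lapply(st, compute_thresholds, k_sd = config$k_sd,
                         tube_potential_kvp = kvp)
    img <- get_image(id)
    for (m in config$materials) {
      # validates that every series really shares the study grid
      masks$voi[[m]] <- propagate_voi(masks$voi[[m]], img)
      thr <- thresholds[[m]]
      thr_rows[[paste(id, m)]] <- data.frame(
        series = id, material = m, kvp = kvp,
        mean_hu = thr$mean_hu, sd_hu = thr$sd_hu,
        lower_hu = thr$lower_hu, upper_hu = thr$upper_hu,
        k_sd = thr$k_sd, source_series = src, stringsAsFactors = FALSE)
    }
    q <- quantify_series(id, img, thresholds, masks$reference, masks$voi,
                         truth = get_truth(id), tip_slice = masks$tip_slice)
    results[[id]] <- q$results
    prof_rows <- c(prof_rows, q$profiles)

    ni <- get_noise_input(id)
    if (!is.null(ni)) {
      noise_rows[[id]] <- data.frame(
        series = id, noise_hu = image_noise(ni$vol, ni$mask),
        stringsAsFactors = FALSE)
    }
    # CNR: tissue reference stats vs water (bath with phantom) of this series
    own <- lapply(config$materials, function(m)
      region_stats(img, masks$reference[[m]], material = m,
                   source_series = id))
    names(own) <- config$materials
    if ("water" %in% config$materials) {
      for (m in setdiff(config$materials, "water")) {
        cnr_rows[[paste(id, m)]] <- data.frame(
          series = id, material = m,
          cnr = cnr(own[[m]], own[["water"]]), stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(
    results = do.call(rbind, c(results, make.row.names = FALSE)),
    thresholds = do.call(rbind, c(thr_rows, make.row.names = FALSE)),
    noise = if (length(noise_rows))
      do.call(rbind, c(noise_rows, make.row.names = FALSE)) else NULL,
    cnr = if (length(cnr_rows))
      do.call(rbind, c(cnr_rows, make.row.names = FALSE)) else NULL,
    profiles = if (length(prof_rows))
      do.call(rbind, c(prof_rows, make.row.names = FALSE)) else NULL,
    config = config,
    provenance = list(seed = config$seed,
                      package = "maraq",
                      version = as.character(packageVersion("maraq")))
  ), class = "artifact_study")
}

#' @export
print.artifact_study <- function(x, ...) {
  cat(sprintf("<artifact_study> %d series x %d materials (seed %d)\n\n",
              length(unique(x$results$series)),
              length(unique(x$results$material)),
              x$provenance$seed))
  r <- x$results
  out <- data.frame(series = r$series, material = r$material,
                    raw = round(r$raw_percent, 1),
                    correction = round(r$correction_percent, 1),
                    corrected = round(r$corrected_percent, 1))
  if (any(!is.na(r$truth_percent))) {
    out$truth <- round(r$truth_percent, 1)
  }
  print(out, row.names = FALSE)
  if (!is.null(x$noise)) {
    cat("\nNoise (HU SD, water bath only):\n")
    n <- x$noise
    print(data.frame(series = n$series, noise_hu = round(n$noise_hu, 2)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.artifact_study <- function(object, ...) {
  r <- object$results
  s <- list(
    n_series = length(unique(r$series)),
    materials = unique(r$material),
    corrected_range = range(r$corrected_percent),
    recovery_error = if (any(!is.na(r$truth_percent)))
      max(abs(r$corrected_percent - r$truth_percent), na.rm = TRUE)
    else NA_real_,
    noise = object$noise, cnr = object$cnr)
  class(s) <- "summary.artifact_study"
  s
}

#' @export
print.summary.artifact_study <- function(x, ...) {
  cat(sprintf("Artifact study: %d series, materials %s\n", x$n_series,
              paste(x$materials, collapse = "/")))
  cat(sprintf("Corrected artifact percentage range: %.1f%% - %.1f%%\n",
              x$corrected_range[1], x$corrected_range[2]))
  if (!is.na(x$recovery_error)) {
    cat(sprintf("Max |corrected - injected truth|: %.2f points\n",
                x$recovery_error))
  }
  if (!is.null(x$cnr)) {
    cat("CNR:\n")
    print(data.frame(series = x$cnr$series, material = x$cnr$material,
                     cnr = round(x$cnr$cnr, 2)), row.names = FALSE)
  }
  invisible(x)
}

#' Write study results to CSV and JSON
#'
#' Writes `results.csv`, `thresholds.csv`, `noise.csv`, `cnr.csv`,
#' `profiles.csv` (per-slice distance profiles) and a combined `study.json`
#' into `dir`. Output is deterministic: re-running the same config and seed
#' reproduces the files byte for byte.
#'
#' @param study an `artifact_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_study_results <- function(study, dir) {
  stopifnot(inherits(study, "artifact_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    if (is.null(df)) return()
    f <- file.path(dir, name)
    write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  emit(study$results, "results.csv")
  emit(study$thresholds, "thresholds.csv")
  emit(study$noise, "noise.csv")
  emit(study$cnr, "cnr.csv")
  emit(study$profiles, "profiles.csv")
  fj <- file.path(dir, "study.json")
  jsonlite::write_json(
    list(provenance = study$provenance,
         results = study$results, thresholds = study$thresholds,
         noise = study$noise, cnr = study$cnr),
    fj, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, fj)
  invisible(files)
}
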