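# Small phantom geometry for fast unit tests: same structure as the default
# study phantom (bath, cortical shell, marrow, tapered stem, reference slab,
# gap, VOI) but coarse voxels and short z extent.
tiny_spec <- function(voxel_spacing_mm = c(2, 2, 4)) {
  phantom_spec(
    bath_width_mm = 120, bath_height_mm = 90,
    femur_outer_radii_mm = c(30, 26), cortical_thickness_mm = 6,
    stem_proximal_axes_mm = c(30, 24), stem_distal_axes_mm = c(20, 22),
    stem_length_mm = 40, voi_length_mm = 40,
    reference_length_mm = 24, reference_gap_mm = 20,
    voxel_spacing_mm = voxel_spacing_mm, air_pad_mm = 4
  )
}

# margins scaled to the tiny geometry (the defaults suit the full-size bath)
tiny_margins <- c(cortical_bone = 1, bone_marrow = 1, water = 6)

tiny_config <- function(series = list("EID-CT 140"), target_percent = 10,
                        seed = 7, spacing = c(2, 2, 4), ...) {
  study_config(series = series, spec = tiny_spec(spacing),
               margins_mm = tiny_margins,
               artifact = if (is.null(target_percent)) list()
                          else list(target_percent = target_percent),
               seed = seed, ...)
}

# random HU volume on a small grid
random_volume <- function(dim = c(8, 7, 6), spacing = c(1, 1, 2),
                          mean = 0, sd = 50, seed = 1) {
  set.seed(seed)
  ct_volume(array(rnorm(prod(dim), mean, sd), dim), spacing)
}

# brute-force per-voxel out-of-range + VOI intersection (independent oracle)
naive_segment <- function(vol, lower, upper, voi) {
  d <- dim(vol$data)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- vol$data[i, j, k]
    out[i, j, k] <- (v < lower || v > upper) && voi$data[i, j, k]
  }
  out
}
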