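test_that("clean phantom voxels carry the protocol's material HU means", {
  vol <- build_phantom(tiny_spec(), reference_protocol("EID-CT 140"))
  codes <- material_codes()
  expect_equal(unique(vol$image$data[vol$labels == codes[["cortical_bone"]]]),
               679.70)
  expect_equal(unique(vol$image$data[vol$labels == codes[["bone_marrow"]]]),
               -674.12)
  expect_equal(unique(vol$image$data[vol$labels == codes[["water"]]]), -0.34)
  expect_equal(unique(vol$image$data[vol$labels == codes[["metal"]]]), 3000)
  expect_equal(unique(vol$image$data[vol$labels == codes[["air"]]]), -1000)
  # all five materials present, no injected artifacts
  expect_setequal(unique(as.vector(vol$labels)), unname(codes))
  expect_false(any(vol$artifact_truth))

  vol2 <- build_phantom(tiny_spec(), reference_protocol("Macro-HTI 140/75"))
  expect_equal(unique(vol2$image$data[vol2$labels == codes[["cortical_bone"]]]),
               595.96)
})

test_that("geometry that does not fit is rejected", {
  expect_error(
    phantom_spec(femur_outer_radii_mm = c(20, 18),
                 stem_proximal_axes_mm = c(40, 30)),
    "stem does not fit")
  expect_error(phantom_spec(femur_outer_radii_mm = c(120, 33)),
               "does not fit inside the water bath")
  expect_error(phantom_spec(cortical_thickness_mm = 40), "marrow")
})

test_that("metal occupies only the prosthesis zone and tapers", {
  spec <- tiny_spec()
  vol <- build_phantom(spec, reference_protocol("EID-CT 140"))
  metal_per_slice <- apply(vol$labels == material_codes()[["metal"]], 3, sum)
  g <- maraq:::phantom_geometry(spec)
  expect_true(all(metal_per_slice[g$ref_slices] == 0))
  in_stem <- metal_per_slice[g$stem_slices]
  expect_true(all(in_stem > 0))
  # proximal cross-section (50x40 -> here 30x24) exceeds the distal tip
  expect_gt(in_stem[length(in_stem)], in_stem[1])
})

test_that("artifact injection matches an independent per-voxel recomputation", {
  spec <- tiny_spec()
  vol0 <- build_phantom(spec, reference_protocol("EID-CT 140"))
  n_streaks <- 6; decay <- 20; axial <- 30; amp <- 600; cutoff <- 150
  seed <- 5
  vol <- inject_artifacts(vol0, amplitude_hu = amp, n_streaks = n_streaks,
                          decay_mm = decay, axial_decay_mm = axial,
                          sharpness = 2, truth_cutoff_hu = cutoff,
                          seed = seed)
  # oracle: loop over voxels, recomputing the streak equation from scratch
  d <- dim(vol0$labels)
  sp <- spec$voxel_spacing_mm
  phi <- maraq:::with_seed(seed, runif(1, 0, 2 * pi))
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  z <- (seq_len(d[3]) - 0.5) * sp[3]
  codes <- material_codes()
  pert <- array(0, d)
  for (k in seq_len(d[3])) {
    if (!any(vol0$labels[, , k] == codes[["metal"]])) next
    az <- 1 / (1 + abs(z[k] - spec$z_tip_mm) / axial)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      lab <- vol0$labels[i, j, k]
      if (!lab %in% codes[c("water", "cortical_bone", "bone_marrow")]) next
      th <- atan2(y[j], x[i])
      r <- sqrt(x[i]^2 + y[j]^2)
      cc <- cos(n_streaks * th + phi)
      pert[i, j, k] <- amp * sign(cc) * abs(cc)^2 * az / (1 + r / decay)
    }
  }
  expect_equal(vol$image$data - vol0$image$data, pert, tolerance = 1e-12)
  expect_identical(vol$artifact_truth, abs(pert) > cutoff)
})

test_that("zero amplitude is a no-op and equal seeds reproduce streaks", {
  vol0 <- build_phantom(tiny_spec(), reference_protocol("EID-CT 140"))
  same <- inject_artifacts(vol0, amplitude_hu = 0, truth_cutoff_hu = 100)
  expect_identical(same$image$data, vol0$image$data)
  expect_false(any(same$artifact_truth))

  a <- inject_artifacts(vol0, amplitude_hu = 500, seed = 9,
                        truth_cutoff_hu = 120)
  b <- inject_artifacts(vol0, amplitude_hu = 500, seed = 9,
                        truth_cutoff_hu = 120)
  expect_identical(a$artifact_truth, b$artifact_truth)
  expect_identical(a$image$data, b$image$data)
  c <- inject_artifacts(vol0, amplitude_hu = 500, seed = 10,
                        truth_cutoff_hu = 120)
  expect_false(identical(a$image$data, c$image$data))

  expect_error(inject_artifacts(vol0, amplitude_hu = 50,
                                truth_cutoff_hu = 120), "exceed")
  bath <- build_water_bath(tiny_spec(), reference_protocol("EID-CT 140"))
  expect_error(inject_artifacts(bath, amplitude_hu = 500), "no metal")
})

test_that("slice-wise truth fraction decays with distance from the stem tip", {
  vol <- inject_artifacts(
    build_phantom(tiny_spec(c(1, 1, 4)), reference_protocol("EID-CT 140")),
    amplitude_hu = 600, truth_cutoff_hu = 150, decay_mm = 20, seed = 3)
  metal_slices <- which(apply(vol$labels == material_codes()[["metal"]],
                              3, any))
  frac <- vapply(metal_slices,
                 function(k) mean(vol$artifact_truth[, , k]), numeric(1))
  # slices are ordered by |z - tip| because the tip is the distal stem end
  expect_true(all(diff(frac) <= 1e-12))
  expect_gt(frac[1], frac[length(frac)])
})

test_that("calibration hits requested ground-truth fractions", {
  spec <- tiny_spec(c(1, 1, 4))
  vol <- build_phantom(spec, reference_protocol("EID-CT 140"))
  voi <- voi_slab_mask(vol)
  marrow <- material_mask(vol, "bone_marrow")
  marrow$data <- marrow$data & voi$data
  for (target in c(10, 30)) {
    amp <- 10 * 150
    m <- calibrate_streak_sharpness(vol, marrow, target, amplitude_hu = amp,
                                    truth_cutoff_hu = 150, seed = 4)
    inj <- inject_artifacts(vol, amplitude_hu = amp, sharpness = m,
                            truth_cutoff_hu = 150, seed = 4)
    got <- 100 * sum(inj$artifact_truth & marrow$data) / sum(marrow$data)
    expect_equal(got, target, tolerance = 0.02)
    # amplitude calibration at the resulting sharpness agrees
    a2 <- calibrate_streak_amplitude(vol, marrow, target, sharpness = m,
                                     truth_cutoff_hu = 150, seed = 4)
    expect_equal(a2, amp, tolerance = 0.05)
  }
})

test_that("additive noise is calibrated, seeded and label-preserving", {
  vol <- build_water_bath(tiny_spec(c(1, 1, 2)),
                          reference_protocol("EID-CT 140"))
  expect_identical(add_noise(vol, 0)$image$data, vol$image$data)
  expect_error(add_noise(vol, -1), "non-negative")

  noisy <- add_noise(vol, 34.62, seed = 21)
  expect_identical(noisy$labels, vol$labels)
  water <- material_mask(noisy, "water")
  expect_gt(sum(water$data), 1e5)
  sd_hat <- stats::sd(noisy$image$data[water$data])
  expect_equal(sd_hat, 34.62, tolerance = 0.02)

  again <- add_noise(vol, 34.62, seed = 21)
  expect_identical(noisy$image$data, again$image$data)
})

test_that("detector-mode simulation reproduces the averaging noise law", {
  s1 <- simulate_detector_noise(1, 20000, seed = 1)
  expect_equal(s1, 1.0, tolerance = 0.02)
  s16 <- simulate_detector_noise(16, 20000, seed = 2)
  expect_equal(s16, 0.25, tolerance = 0.02)
  s8 <- simulate_detector_noise(8, 20000, seed = 3)
  expect_equal(s8 / s16, sqrt(2), tolerance = 0.03)
  expect_error(simulate_detector_noise(0, 2000), "positive")
  expect_error(simulate_detector_noise(4, 10), ">= 1000")
})

test_that("acquisition sets share one grid, pair water companions and seed deterministically", {
  spec <- tiny_spec()
  set <- simulate_acquisition_set(
    spec, protocols = list("EID-CT 140", "Macro-HTI 140/75"),
    artifact = list(target_percent = 10), seed = 31)
  expect_named(set$series, c("EID-CT 140", "Macro-HTI 140/75"))
  s1 <- set$series[[1]]; s2 <- set$series[[2]]
  expect_true(same_grid(s1$phantom$image, s2$phantom$image))
  expect_true(same_grid(s1$phantom$image, s1$water_only$image))
  # water-only companion really is phantom-free
  expect_false(any(s1$water_only$labels > material_codes()[["water"]]))

  set2 <- simulate_acquisition_set(
    spec, protocols = list("EID-CT 140", "Macro-HTI 140/75"),
    artifact = list(target_percent = 10), seed = 31)
  expect_identical(s1$phantom$image$data,
                   set2$series[[1]]$phantom$image$data)
  expect_identical(s2$water_only$image$data,
                   set2$series[[2]]$water_only$image$data)
})

test_that("Chess noise defaults to sqrt(2) times the same-kVp Macro noise", {
  macro <- acquisition_protocol("PCD", "Macro", 140, 75,
    material_means_hu = c(cortical_bone = 595.96, bone_marrow = -647.91,
                          water = -0.03),
    noise_sd_hu = 55.23)
  chess <- acquisition_protocol("PCD", "Chess", 140, 75,
    material_means_hu = c(cortical_bone = 614.68, bone_marrow = -661.37,
                          water = 0.38))
  set <- simulate_acquisition_set(tiny_spec(), list(macro, chess), seed = 1)
  expect_equal(set$series[["Chess-HTI 140/75"]]$sigma_hu, sqrt(2) * 55.23)
  expect_equal(set$series[["Chess-HTI 140/75"]]$sigma_hu, 78.10,
               tolerance = 2e-4)
  # no Macro partner and no explicit SD -> error
  expect_error(simulate_acquisition_set(tiny_spec(), list(chess), seed = 1),
               "no noise SD")
})
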