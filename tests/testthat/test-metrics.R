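mask_of <- function(idx, dim, spacing = c(1, 1, 1)) {
  m <- array(FALSE, dim)
  m[idx] <- TRUE
  ct_mask(m, spacing)
}

test_that("artifact percentage is the artifact share of the VOI", {
  d <- c(10, 10, 10)
  voi <- mask_of(1:900, d)
  art <- mask_of(1:90, d)
  expect_equal(artifact_fraction(art, voi), 10)
  expect_equal(artifact_fraction(mask_of(integer(0), d), voi), 0)
  expect_equal(artifact_fraction(voi, voi), 100)
  expect_error(artifact_fraction(art, mask_of(integer(0), d)), "empty")
  # voxels outside the VOI never count
  art2 <- mask_of(c(1:90, 901:950), d)
  expect_equal(artifact_fraction(art2, voi), 10)
})

test_that("artifact percentage is additive over disjoint VOI partitions", {
  set.seed(3)
  d <- c(12, 12, 6)
  art <- mask_of(sample(prod(d), 150), d)
  voi_all <- mask_of(1:prod(d), d)
  half1 <- mask_of(1:(prod(d) / 2), d)
  half2 <- mask_of((prod(d) / 2 + 1):prod(d), d)
  f <- artifact_fraction(art, voi_all)
  f1 <- artifact_fraction(art, half1)
  f2 <- artifact_fraction(art, half2)
  w1 <- sum(half1$data) / sum(voi_all$data)
  expect_equal(f, w1 * f1 + (1 - w1) * f2, tolerance = 1e-12)
})

test_that("correction factor matches the Gaussian misclassification rates", {
  d <- c(100, 100, 100)
  vol <- random_volume(d, mean = -0.27, sd = 32.95, seed = 6)
  ref <- mask_of(1:prod(d), d, vol$spacing_mm)
  st <- region_stats(vol, ref)
  thr3 <- compute_thresholds(st, k_sd = 3)
  cf3 <- correction_factor(vol, ref, thr3)
  expect_equal(cf3, 100 * 2 * pnorm(-3), tolerance = 0.12)
  expect_equal(round(cf3, 1), 0.3)  # the "approximately 0.3%" rate
  thr2 <- compute_thresholds(st, k_sd = 2)
  expect_equal(correction_factor(vol, ref, thr2), 100 * 2 * pnorm(-2),
               tolerance = 0.03)
  # constant volume inside bounds -> 0
  cv <- ct_volume(array(5, c(4, 4, 2)), c(1, 1, 1))
  expect_equal(correction_factor(cv, mask_of(1:32, c(4, 4, 2)),
                                 threshold_pair(0, 10)), 0)
})

test_that("correction factor is the artifact fraction with the reference as VOI", {
  vol <- random_volume(c(20, 20, 10), sd = 40, seed = 2)
  ref <- mask_of(1:2000, dim(vol$data), vol$spacing_mm)
  thr <- threshold_pair(-60, 60)
  expect_equal(correction_factor(vol, ref, thr),
               artifact_fraction(classify_out_of_range(vol, thr), ref))
})

test_that("corrected percentages subtract and floor at zero", {
  expect_equal(corrected_fraction(10.0, 0.3), 9.7)
  expect_equal(corrected_fraction(0.2, 0.3), 0)
  expect_equal(corrected_fraction(5.0, 0.0), 5.0)
  expect_equal(corrected_fraction(c(10, 0.2), c(0.3, 0.3)), c(9.7, 0))
  expect_error(corrected_fraction(101, 0), "0, 100")
})

test_that("noise is the water-bath SD and scales sqrt(2) between modes", {
  cv <- ct_volume(array(7, c(5, 5, 4)), c(1, 1, 1))
  allm <- mask_of(1:100, c(5, 5, 4))
  expect_equal(image_noise(cv, allm), 0)

  spec <- tiny_spec(c(1, 1, 2))
  prot <- reference_protocol("EID-CT 140")
  w <- add_noise(build_water_bath(spec, prot), 32.95, seed = 5)
  wm <- material_mask(w, "water")
  expect_equal(image_noise(w$image, wm), 32.95, tolerance = 0.02)

  macro <- add_noise(build_water_bath(spec, prot), 55.23, seed = 6)
  chess <- add_noise(build_water_bath(spec, prot), 55.23 * sqrt(2), seed = 7)
  ratio <- image_noise(chess$image, wm) / image_noise(macro$image, wm)
  expect_equal(ratio, sqrt(2), tolerance = 0.02)
})

test_that("CNR reproduces published spot values and its invariances", {
  cort <- material_stats(595.96, 125.94)
  marr <- material_stats(-647.91, 112.03)
  watr <- material_stats(-0.03, 56.87)
  expect_equal(round(cnr(cort, watr), 2), 6.10)
  expect_equal(round(cnr(marr, watr), 2), 7.29)
  expect_equal(cnr(material_stats(5, 10), material_stats(5, 12)), 0)

  # symmetric in contrast sign, invariant under a global HU shift
  expect_equal(cnr(watr, cort), cnr(cort, watr))
  shift <- function(s, c) material_stats(s$mean_hu + c, s$sd_hu)
  expect_equal(cnr(shift(cort, 80), shift(watr, 80)), cnr(cort, watr))

  # literal water-SD denominator is available but differs
  expect_equal(cnr(cort, watr, method = "water_sd"),
               abs(595.96 + 0.03) / 56.87)
  expect_error(cnr(material_stats(1, 0), material_stats(0, 0)), "zero")
})

test_that("distance profiles are flat for uniform artifacts and decay for streaks", {
  d <- c(6, 6, 8)
  voi <- ct_mask(array(TRUE, d), c(1, 1, 2))
  art <- ct_mask(array(rep(c(TRUE, FALSE), length.out = prod(d)), d),
                 c(1, 1, 2))
  prof <- distance_profile(art, voi, reference_slice = 1)
  expect_equal(nrow(prof), 8)
  expect_equal(prof$distance_mm, (0:7) * 2)
  expect_true(all(abs(prof$percent - 50) < 1e-9))

  vol <- inject_artifacts(
    build_phantom(tiny_spec(c(2, 2, 4)), reference_protocol("EID-CT 140")),
    amplitude_hu = 600, truth_cutoff_hu = 150, seed = 3)
  voi2 <- voi_slab_mask(vol)
  art2 <- ct_mask(vol$artifact_truth, vol$image$spacing_mm)
  tip <- maraq:::phantom_geometry(vol$spec)$voi_slices[1]
  prof2 <- distance_profile(art2, voi2, tip)
  rho <- cor(prof2$distance_mm, prof2$percent, method = "spearman")
  expect_lte(rho, 0)

  single <- ct_mask(array(c(rep(FALSE, prod(d) - 36), rep(TRUE, 36)), d),
                    c(1, 1, 2))
  expect_error(distance_profile(art, single, 1), "at least 2 slices")
})
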