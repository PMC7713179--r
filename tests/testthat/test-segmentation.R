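test_that("region statistics use the sample SD and report counts", {
  v <- ct_volume(array(5, c(5, 2, 1)), c(1, 1, 1))
  m <- ct_mask(array(TRUE, c(5, 2, 1)), c(1, 1, 1))
  st <- region_stats(v, m, material = "water")
  expect_equal(st$mean_hu, 5)
  expect_equal(st$sd_hu, 0)
  expect_equal(st$n_voxels, 10)

  v2 <- ct_volume(array(c(0, 2, 9, 9), c(2, 2, 1)), c(1, 1, 1))
  m2 <- ct_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)), c(1, 1, 1))
  st2 <- region_stats(v2, m2)
  expect_equal(st2$mean_hu, 1)
  expect_equal(st2$sd_hu, sqrt(2), tolerance = 1e-6)

  expect_error(region_stats(v, ct_mask(array(FALSE, c(5, 2, 1)), c(1, 1, 1))),
               "at least 2")
})

test_that("region statistics recover generator parameters on Gaussian data", {
  # water-only reference conditions: mean -0.27 HU, SD 32.95 HU
  v <- random_volume(c(60, 60, 40), mean = -0.27, sd = 32.95, seed = 8)
  m <- ct_mask(array(TRUE, dim(v$data)), v$spacing_mm)
  st <- region_stats(v, m)
  expect_equal(st$sd_hu, 32.95, tolerance = 0.02)
  expect_lt(abs(st$mean_hu - (-0.27)), 3 * 32.95 / sqrt(st$n_voxels))
})

test_that("thresholds are mean +/- k SD", {
  thr <- compute_thresholds(material_stats(0, 10), k_sd = 3)
  expect_equal(c(thr$lower_hu, thr$upper_hu), c(-30, 30))
  thr2 <- compute_thresholds(material_stats(679.70, 80.93, "cortical_bone"))
  expect_equal(round(c(thr2$lower_hu, thr2$upper_hu), 2), c(436.91, 922.49))
  thr3 <- compute_thresholds(material_stats(-674.12, 81.22, "bone_marrow"))
  expect_equal(round(c(thr3$lower_hu, thr3$upper_hu), 2),
               c(-917.78, -430.46))
  expect_error(compute_thresholds(material_stats(0, 1), k_sd = 0),
               "positive")
  expect_error(threshold_pair(10, 5), "exceed")
})

test_that("out-of-range classification treats the bounds as normal tissue", {
  v <- ct_volume(array(c(400, 500, 1000, 436.91, 922.49, 800), c(6, 1, 1)),
                 c(1, 1, 1))
  thr <- threshold_pair(436.91, 922.49)
  got <- classify_out_of_range(v, thr)
  expect_identical(as.vector(got$data),
                   c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("segmentation equals the naive per-voxel oracle on random volumes", {
  for (seed in 1:3) {
    vol <- random_volume(c(12, 10, 8), mean = 100, sd = 300, seed = seed)
    set.seed(seed + 100)
    voi <- ct_mask(array(runif(prod(dim(vol$data))) > 0.3, dim(vol$data)),
                   vol$spacing_mm)
    thr <- threshold_pair(-150, 420)
    got <- segment_artifacts(vol, thr, voi)
    expect_identical(got$data, naive_segment(vol, -150, 420, voi))
  }
})

test_that("wider thresholds never enlarge the artifact mask and shifts cancel", {
  vol <- random_volume(c(16, 16, 6), sd = 120, seed = 4)
  st <- material_stats(0, 100)
  prev <- NULL
  for (k in c(1, 2, 3, 4)) {
    mk <- classify_out_of_range(vol, compute_thresholds(st, k_sd = k))$data
    if (!is.null(prev)) expect_true(all(!mk | prev))  # mk subset of prev
    prev <- mk
  }
  thr <- compute_thresholds(st, k_sd = 2)
  shifted <- vol
  shifted$data <- vol$data + 123.4
  thr_shift <- threshold_pair(thr$lower_hu + 123.4, thr$upper_hu + 123.4)
  expect_identical(classify_out_of_range(vol, thr)$data,
                   classify_out_of_range(shifted, thr_shift)$data)
})

test_that("metric erosion respects mm margins and anisotropic spacing", {
  # 10 mm cube at 1 mm spacing, 2 mm margin -> 6 mm cube
  g <- array(FALSE, c(14, 14, 14))
  g[3:12, 3:12, 3:12] <- TRUE
  er <- erode_mask_mm(ct_mask(g, c(1, 1, 1)), 2)
  expect_equal(sum(er$data), 6^3)
  expect_true(all(which(er$data, arr.ind = TRUE) >= 5) &&
                all(which(er$data, arr.ind = TRUE) <= 10))

  # margin 0 is the identity, oversized margins empty the mask
  expect_identical(erode_mask_mm(ct_mask(g, c(1, 1, 1)), 0)$data, g)
  expect_equal(sum(erode_mask_mm(ct_mask(g, c(1, 1, 1)), 6)$data), 0)

  # anisotropic: 2 mm z-spacing erodes one slice per face, not two
  er2 <- erode_mask_mm(ct_mask(g, c(1, 1, 2)), 2)
  expect_equal(sum(er2$data), 6 * 6 * 8)

  # brute-force distance oracle on a random small mask
  set.seed(9)
  d <- c(9, 8, 7); sp <- c(1, 1.5, 2)
  m <- array(runif(prod(d)) > 0.35, d)
  bg <- which(!m, arr.ind = TRUE)
  margin <- 1.6
  keep <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!m[i, j, k]) next
    dd <- min((bg[, 1] - i)^2 * sp[1]^2 + (bg[, 2] - j)^2 * sp[2]^2 +
                (bg[, 3] - k)^2 * sp[3]^2)
    keep[i, j, k] <- sqrt(dd) > margin
  }
  expect_identical(erode_mask_mm(ct_mask(m, sp), margin)$data, keep)
})

test_that("segmentation respects the VOI and captures strong streaks", {
  vol <- build_phantom(tiny_spec(), reference_protocol("EID-CT 140"))
  sigma <- 32.95
  inj <- inject_artifacts(vol, amplitude_hu = 10 * sigma * 3,
                          truth_cutoff_hu = 3 * sigma, seed = 2)
  noisy <- add_noise(inj, sigma, seed = 3)
  voi <- voi_slab_mask(noisy)
  marrow <- material_mask(noisy, "bone_marrow")
  voi$data <- voi$data & marrow$data
  thr <- compute_thresholds(material_stats(-674.12, sigma), k_sd = 3)
  seg <- segment_artifacts(noisy$image, thr, voi)
  expect_true(all(!seg$data | voi$data))          # subset of the VOI
  truth_in_voi <- inj$artifact_truth & voi$data
  # amplitude is 10x the classification half-width: essentially every true
  # artifact voxel must be detected
  expect_gt(sum(seg$data & truth_in_voi) / sum(truth_in_voi), 0.97)

  # all voxels in range -> empty mask; disjoint VOI -> empty result
  clean <- build_phantom(tiny_spec(), reference_protocol("EID-CT 140"))
  seg0 <- segment_artifacts(clean$image,
                            compute_thresholds(material_stats(-674.12, 10)),
                            material_mask(clean, "bone_marrow"))
  expect_equal(sum(seg0$data), 0)
})

test_that("out-of-range fraction on Gaussian data matches 2*pnorm(-3)", {
  n <- c(80, 80, 60)
  vol <- random_volume(n, mean = 50, sd = 20, seed = 12)
  thr <- threshold_pair(50 - 3 * 20, 50 + 3 * 20)
  frac <- mean(classify_out_of_range(vol, thr)$data)
  p <- 2 * pnorm(-3)
  se <- sqrt(p * (1 - p) / prod(n))
  expect_lt(abs(frac - p), 3 * se)
})
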