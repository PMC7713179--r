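#' Add Gaussian image noise to a volume
#'
#' Adds zero-mean Gaussian noise of standard deviation `sigma_hu` to every
#' voxel. Additive Gaussian noise in HU is the noise model throughout the
#' simulator, matching how noise is measured downstream (the SD of CT
#' numbers in a water-bath region). Labels and the ground-truth artifact
#' mask are untouched.
#'
#' @param vol a `labeled_volume`.
#' @param sigma_hu noise SD in HU (>= 0; 0 is a no-op).
#' @param seed integer seed; the same seed reproduces the volume exactly.
#' @return the `labeled_volume` with noisy image.
#' @export
add_noise <- function(vol, sigma_hu, seed = 1) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (!is_len(sigma_hu, 1) || sigma_hu < 0) {
    stopf("'sigma_hu' must be a non-negative HU value")
  }
  if (sigma_hu == 0) return(vol)
  n <- length(vol$image$data)
  vol$image$data <- vol$image$data +
    array(with_seed(seed, rnorm(n, 0, sigma_hu)), dim(vol$image$data))
  vol
}

#' Simulate the detector-binning noise law
#'
#' Each image pixel of the photon-counting detector averages a number of
#' independent subpixel measurements; configurations that assign only half
#' the subpixels to a threshold setting (Chess vs Macro mode) are predicted
#' to raise image noise by sqrt(2). This simulator draws `n_samples` pixels,
#' each the mean of `n_subpixels_used` independent unit-variance samples,
#' and returns the empirical SD of the pixel values (expectation
#' `1 / sqrt(n_subpixels_used)`).
#'
#' @param n_subpixels_used subpixels contributing to each pixel (>= 1).
#' @param n_samples number of simulated pixels (>= 1000).
#' @param seed integer seed.
#' @return empirical SD (unitless, relative to subpixel SD).
#' @examples
#' s8 <- simulate_detector_noise(8, 5e4, seed = 1)
#' s16 <- simulate_detector_noise(16, 5e4, seed = 2)
#' s8 / s16  # ~ sqrt(2), "approximately a factor of 1.4"
#' @export
simulate_detector_noise <- function(n_subpixels_used, n_samples, seed = 1) {
  if (!is_count(n_subpixels_used, min = 1)) {
    stopf("'n_subpixels_used' must be a positive integer")
  }
  if (!is_count(n_samples, min = 1000)) {
    stopf("'n_samples' must be an integer >= 1000")
  }
  means <- with_seed(seed, {
    rowMeans(matrix(rnorm(n_samples * n_subpixels_used),
                    nrow = n_samples))
  })
  sd(means)
}
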