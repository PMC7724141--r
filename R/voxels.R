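#' Sample ground-truth voxels with 2D Gaussian receptive fields
#'
#' Draws a population of simulated voxels whose receptive-field centers cover
#' one or both visual hemifields uniformly (by area, over a disk of radius
#' `extent_deg`) and whose size grows linearly with eccentricity, emulating
#' the size-eccentricity scaling seen in retinotopic maps. Gaussian noise is
#' added to the sizes and the result floored at a small positive value.
#'
#' @param n_voxels number of voxels to draw (>= 0).
#' @param hemifield `"left"`, `"right"`, or `"both"`: which visual hemifield
#'   the centers occupy. A right-hemifield voxel has x > 0.
#' @param size_slope linear growth of receptive-field size (sigma, degrees)
#'   per degree of eccentricity (>= 0; default 0.2).
#' @param size_intercept receptive-field size at fixation, degrees
#'   (default 0.5).
#' @param size_noise_sd SD of Gaussian noise added to sizes (default 0.3).
#' @param extent_deg maximum center eccentricity (default 16).
#' @param hrf_peak_s,hrf_undershoot_s HRF delay parameters given to every
#'   voxel (defaults 6 and 16 s).
#' @param baseline,amplitude signal offset and gain (defaults 0 and 1).
#' @param noise_sd SD of additive measurement noise per TR (default 0).
#' @param sigma_floor lower bound applied to sizes after noise (default 0.05).
#' @param seed RNG seed for reproducibility (optional).
#' @return data.frame with one row per voxel: `x_deg`, `y_deg`, `sigma_deg`,
#'   `angle_deg`, `ecc_deg`, `hrf_peak_s`, `hrf_undershoot_s`, `baseline`,
#'   `amplitude`, `noise_sd`.
#' @examples
#' vox <- sample_ground_truth_voxels(100, hemifield = "right", seed = 1)
#' all(vox$x_deg > 0)
#' @export
sample_ground_truth_voxels <- function(n_voxels, hemifield = c("both", "left", "right"),
                                       size_slope = 0.2, size_intercept = 0.5,
                                       size_noise_sd = 0.3, extent_deg = 16,
                                       hrf_peak_s = 6, hrf_undershoot_s = 16,
                                       baseline = 0, amplitude = 1,
                                       noise_sd = 0, sigma_floor = 0.05,
                                       seed = NULL) {
  stopifnot(n_voxels >= 0, size_slope >= 0, size_intercept > 0, sigma_floor > 0)
  hemifield <- match.arg(hemifield)
  if (n_voxels == 0) {
    return(data.frame(
      x_deg = numeric(0), y_deg = numeric(0), sigma_deg = numeric(0),
      angle_deg = numeric(0), ecc_deg = numeric(0),
      hrf_peak_s = numeric(0), hrf_undershoot_s = numeric(0),
      baseline = numeric(0), amplitude = numeric(0), noise_sd = numeric(0)
    ))
  }
  with_seed(seed, {
    # area-uniform over the (hemi-)disk
    ecc <- extent_deg * sqrt(stats::runif(n_voxels))
    ang <- switch(hemifield,
      both = stats::runif(n_voxels, 0, 360),
      right = wrap_angle(stats::runif(n_voxels, -90, 90)),
      left = stats::runif(n_voxels, 90, 270)
    )
    xy <- polar2cart(ang, ecc)
    sigma <- size_intercept + size_slope * ecc +
      stats::rnorm(n_voxels, 0, size_noise_sd)
    sigma <- pmax(sigma, sigma_floor)
    data.frame(
      x_deg = xy$x_deg, y_deg = xy$y_deg, sigma_deg = sigma,
      angle_deg = ang, ecc_deg = ecc,
      hrf_peak_s = hrf_peak_s, hrf_undershoot_s = hrf_undershoot_s,
      baseline = baseline, amplitude = amplitude, noise_sd = noise_sd
    )
  })
}
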