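#' pRF forward model: aperture overlap plus hemodynamics
#'
#' The neural drive of a voxel with a 2D Gaussian receptive field is the
#' overlap between each aperture frame and the Gaussian, normalized so that a
#' full-field frame yields drive 1. The BOLD prediction is
#' `amplitude * (drive convolved with HRF) + baseline`. The same code path is
#' used both to simulate voxels and to generate model predictions during
#' fitting, so noiseless self-consistency is exact by construction.
#'
#' @name forward_model
NULL

# Unit-sum Gaussian receptive-field weights over the pixel grid of a
# (flattened) movie. mm is the result of movie_matrix().
gaussian_rf_weights <- function(mm, x, y, sigma) {
  g <- exp(-((mm$x - x)^2 + (mm$y - y)^2) / (2 * sigma^2))
  s <- sum(g)
  if (s <= 0) {
    # pathological: center far outside the grid; fall back to nearest pixel
    g[which.min((mm$x - x)^2 + (mm$y - y)^2)] <- 1
    s <- 1
  }
  g / s
}

# Neural drive time course: TR-length vector, full-field frame -> 1.
# Uses the separable (rank-1 frame) fast path when available: the overlap of
# an outer-product frame with a separable Gaussian factorizes into row and
# column sums.
prf_drive <- function(mm, x, y, sigma) {
  if (!is.null(mm$sep_R)) {
    gy <- exp(-(mm$ys - y)^2 / (2 * sigma^2))
    gx <- exp(-(mm$xs - x)^2 / (2 * sigma^2))
    denom <- sum(gy) * sum(gx)
    if (denom > 0) {
      return(as.vector((mm$sep_R %*% gy) * (mm$sep_C %*% gx)) / denom)
    }
  }
  as.vector(mm$mat %*% gaussian_rf_weights(mm, x, y, sigma))
}

#' Predict the BOLD time series of a pRF parameter set
#'
#' @param prf_params list or one-row data.frame with `x_deg`, `y_deg`,
#'   `sigma_deg`, and optionally `hrf_peak_s`, `hrf_undershoot_s`,
#'   `baseline`, `amplitude` (defaults 6, 16, 0, 1).
#' @param movie a [stimulus_movie].
#' @return numeric vector, one predicted BOLD value per TR.
#' @examples
#' mov <- make_bar_aperture_sequence(grid_size = 48)
#' ts <- predict_bold(list(x_deg = 5, y_deg = 0, sigma_deg = 1), mov)
#' @export
predict_bold <- function(prf_params, movie) {
  p <- as.list(prf_params)
  if (is.null(p$hrf_peak_s)) p$hrf_peak_s <- 6
  if (is.null(p$hrf_undershoot_s)) p$hrf_undershoot_s <- 16
  if (is.null(p$baseline)) p$baseline <- 0
  if (is.null(p$amplitude)) p$amplitude <- 1
  if (p$sigma_deg <= 0) stop("sigma_deg must be > 0")
  mm <- movie_matrix(movie)
  drive <- prf_drive(mm, p$x_deg, p$y_deg, p$sigma_deg)
  hrf <- hrf_kernel(movie$tr_s, p$hrf_peak_s, p$hrf_undershoot_s)
  p$amplitude * convolve_hrf(drive, hrf) + p$baseline
}

#' Simulate a retinotopic mapping run
#'
#' Drives each ground-truth voxel with the aperture movie through the shared
#' forward model and adds white Gaussian noise per TR.
#'
#' @param movie a [stimulus_movie].
#' @param voxels data.frame from [sample_ground_truth_voxels()].
#' @param seed RNG seed for the noise (optional).
#' @return voxel x TR matrix of simulated BOLD.
#' @export
simulate_retinotopy_run <- function(movie, voxels, seed = NULL) {
  stopifnot(inherits(movie, "stimulus_movie"), nrow(voxels) >= 1)
  mm <- movie_matrix(movie)
  n_tr <- nrow(mm$mat)
  bold <- matrix(0, nrow(voxels), n_tr)
  for (v in seq_len(nrow(voxels))) {
    p <- voxels[v, ]
    drive <- prf_drive(mm, p$x_deg, p$y_deg, p$sigma_deg)
    hrf <- hrf_kernel(movie$tr_s, p$hrf_peak_s, p$hrf_undershoot_s)
    bold[v, ] <- p$amplitude * convolve_hrf(drive, hrf) + p$baseline
  }
  with_seed(seed, {
    noise_sd <- voxels$noise_sd
    if (any(noise_sd > 0)) {
      bold <- bold + matrix(stats::rnorm(length(bold), 0, rep(noise_sd, n_tr)),
                            nrow(voxels), n_tr)
    }
    bold
  })
}
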