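#' Retinotopy summaries: coverage, polar-angle volume, size scaling
#'
#' Summaries of a fitted pRF population: the visual-field coverage map
#' (pointwise maximum of unit-height pRF Gaussians), the fractional volume of
#' voxels representing each polar angle, and the linear relation between
#' receptive-field size and eccentricity.
#'
#' @name prf_summaries
NULL

#' Aggregate field-of-view coverage map
#'
#' Each grid coordinate is assigned the maximum over voxels of a unit-height
#' 2D Gaussian centered at that voxel's pRF center with SD equal to its size,
#' so the value at any pRF center is exactly 1.
#'
#' @param fits data.frame with `x_deg`, `y_deg`, `sigma_deg` (one row per
#'   voxel); must be nonempty.
#' @param extent_deg half-width of the map in degrees (default 16).
#' @param grid_size pixels per side (default 101).
#' @return object of class `fov_map`: list with `values` (grid_size x
#'   grid_size matrix, y by x, values in [0, 1]), `x`, `y` coordinate vectors.
#' @export
aggregate_fov <- function(fits, extent_deg = 16, grid_size = 101) {
  if (nrow(fits) == 0) stop("cannot aggregate an empty fit set")
  xs <- pixel_grid(grid_size, extent_deg)
  ys <- pixel_grid(grid_size, extent_deg)
  vals <- matrix(0, grid_size, grid_size)
  for (v in seq_len(nrow(fits))) {
    d2 <- outer(ys - fits$y_deg[v], xs - fits$x_deg[v],
                function(dy, dx) dy^2 + dx^2)
    vals <- pmax(vals, exp(-d2 / (2 * fits$sigma_deg[v]^2)))
  }
  structure(list(values = vals, x = xs, y = ys), class = "fov_map")
}

#' Fractional volume of voxels per polar-angle bin
#'
#' Histogram of pRF polar angles with counts normalized by the total number
#' of voxels, so the fractions sum to 1.
#'
#' @param fits data.frame with an `angle_deg` column; must be nonempty.
#' @param n_bins number of equal angular bins over [0, 360) (>= 2,
#'   default 8).
#' @return data.frame with `bin_center_deg` and `fraction`.
#' @export
polar_angle_histogram <- function(fits, n_bins = 8) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (nrow(fits) == 0) stop("empty fit set")
  width <- 360 / n_bins
  bin <- floor(wrap_angle(fits$angle_deg) / width) + 1
  counts <- tabulate(bin, nbins = n_bins)
  data.frame(
    bin_center_deg = (seq_len(n_bins) - 0.5) * width,
    fraction = counts / nrow(fits)
  )
}

#' Linear size-eccentricity relation of a pRF population
#'
#' Ordinary least-squares regression of receptive-field size on eccentricity,
#' with the Pearson correlation and its two-sided p value.
#'
#' @param fits data.frame with `sigma_deg` and `ecc_deg` columns; at least 3
#'   rows with nonzero eccentricity variance.
#' @return list with `slope`, `intercept`, `pearson_r`, `p`, `ci_slope`
#'   (95% confidence interval on the slope), `n`.
#' @export
size_eccentricity_stats <- function(fits) {
  if (nrow(fits) < 3) stop("need at least 3 fits")
  if (stats::var(fits$ecc_deg) < 1e-12) {
    stop("zero variance in eccentricity")
  }
  fit <- stats::lm(sigma_deg ~ ecc_deg, data = fits)
  ct <- stats::cor.test(fits$ecc_deg, fits$sigma_deg)
  ci <- stats::confint(fit, "ecc_deg", level = 0.95)
  list(
    slope = unname(stats::coef(fit)["ecc_deg"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    pearson_r = unname(ct$estimate), p = ct$p.value,
    ci_slope = as.numeric(ci), n = nrow(fits)
  )
}
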