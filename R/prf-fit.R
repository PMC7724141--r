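#' Two-stage population receptive field fitting
#'
#' Voxel time series from bar-sweep mapping runs are fit with a 2D Gaussian
#' receptive-field model in three phases, mirroring standard practice:
#' (1) a sparse, coarse grid search over center and size using a spatially
#' downsampled effective stimulus, with amplitude and baseline profiled out as
#' a linear subproblem at each candidate; (2) a grid search over the two HRF
#' delay parameters (time to peak and time to undershoot) with the spatial
#' parameters held at the coarse solution; (3) a bounded quasi-Newton
#' refinement of all nonlinear parameters against the full-resolution
#' stimulus, seeded by the previous phases.
#'
#' @name prf_fitting
NULL

#' Default coarse search grid for pRF fitting
#'
#' Centers span the display extent in 2 degree steps; sizes are log-spaced
#' from 0.5 to 8 degrees.
#'
#' @param extent_deg half-width of the search range in degrees (default 16).
#' @param step_deg grid step for the centers (default 2).
#' @param sigmas candidate receptive-field sizes (default 0.5, 1, 2, 4, 8).
#' @return list with components `x`, `y`, `sigma`.
#' @export
default_grid_spec <- function(extent_deg = 16, step_deg = 2,
                              sigmas = c(0.5, 1, 2, 4, 8)) {
  g <- seq(-extent_deg, extent_deg, by = step_deg)
  list(x = g, y = g, sigma = sigmas)
}

# Orthonormal basis of the nuisance space (intercept + linear trend) for a
# series of length n. Fitted time series are compared after projecting this
# space out of both data and prediction, so that per-run detrending of the
# data cannot create model mismatch.
trend_basis <- function(n) {
  tt <- seq_len(n)
  qr.Q(qr(cbind(1, tt - mean(tt))))
}

project_out_trend <- function(x, Q = trend_basis(NROW(x))) {
  res <- x - Q %*% crossprod(Q, x)
  if (is.null(dim(x))) as.vector(res) else res
}

# Profile amplitude and baseline (plus a linear trend nuisance) for
# predictor p against response y. Returns amplitude, baseline, rss,
# r2 (1 - SSR/SST about the mean).
profile_linear <- function(p, y, Q = trend_basis(length(y))) {
  pc <- project_out_trend(p, Q)
  yc <- project_out_trend(y, Q)
  vp <- sum(pc^2)
  sst <- sum(yc^2)
  if (vp < 1e-12 || sst < 1e-12) {
    return(list(amplitude = 0, baseline = mean(y), rss = sst,
                r2 = 0, degenerate = TRUE))
  }
  a <- sum(pc * yc) / vp
  rss <- sst - a^2 * vp
  list(amplitude = a, baseline = mean(y) - a * mean(p), rss = rss,
       r2 = 1 - rss / sst, degenerate = FALSE)
}

# Precompute HRF-convolved predictions for every grid candidate on a
# (typically downsampled) movie. Returns candidate parameter table and a
# TR x n_candidates prediction matrix.
build_grid_predictions <- function(movie, grid_spec,
                                   hrf_peak_s = 6, hrf_undershoot_s = 16) {
  cand <- expand.grid(x = grid_spec$x, y = grid_spec$y,
                      sigma = grid_spec$sigma, KEEP.OUT.ATTRS = FALSE)
  if (nrow(cand) == 0) stop("empty search grid")
  mm <- movie_matrix(movie)
  G <- matrix(0, ncol(mm$mat), nrow(cand))
  for (k in seq_len(nrow(cand))) {
    G[, k] <- gaussian_rf_weights(mm, cand$x[k], cand$y[k], cand$sigma[k])
  }
  drives <- mm$mat %*% G
  hrf <- hrf_kernel(movie$tr_s, hrf_peak_s, hrf_undershoot_s)
  pred <- convolve_hrf(drives, hrf)
  list(candidates = cand, pred = pred)
}

#' Coarse grid search for pRF parameters
#'
#' Evaluates every candidate (x, y, sigma) of `grid_spec` against the voxel
#' time series, solving amplitude and baseline in closed form per candidate,
#' and returns the candidate with the smallest residual sum of squares.
#'
#' @param ts numeric vector, one BOLD value per TR.
#' @param movie_downsampled the (downsampled) effective stimulus, a
#'   [stimulus_movie]; see [downsample_movie()].
#' @param grid_spec list with `x`, `y`, `sigma` candidate vectors (default
#'   [default_grid_spec()]).
#' @param grid_pred optional precomputed result of the internal prediction
#'   builder, to share work across voxels (used by [fit_prf()]).
#' @param hrf_peak_s,hrf_undershoot_s HRF delays assumed during the grid
#'   stage (defaults 6 and 16 s).
#' @return list with `x_deg`, `y_deg`, `sigma_deg`, `amplitude`, `baseline`,
#'   `r2`, and `low_r2` flag (TRUE when the series is flat or no candidate
#'   explains variance).
#' @export
coarse_grid_fit <- function(ts, movie_downsampled, grid_spec = default_grid_spec(),
                            grid_pred = NULL, hrf_peak_s = 6,
                            hrf_undershoot_s = 16) {
  if (is.null(grid_pred)) {
    grid_pred <- build_grid_predictions(movie_downsampled, grid_spec,
                                        hrf_peak_s, hrf_undershoot_s)
  }
  pred <- grid_pred$pred
  cand <- grid_pred$candidates
  Q <- trend_basis(length(ts))
  yc <- project_out_trend(ts, Q)
  sst <- sum(yc^2)
  pc <- project_out_trend(pred, Q)
  vp <- colSums(pc^2)
  cov <- as.vector(crossprod(pc, yc))
  ok <- vp > 1e-12
  r2 <- numeric(nrow(cand))
  if (sst > 1e-12) r2[ok] <- cov[ok]^2 / (vp[ok] * sst)
  best <- which.max(r2)
  a <- if (vp[best] > 1e-12 && sst > 1e-12) cov[best] / vp[best] else 0
  list(
    x_deg = cand$x[best], y_deg = cand$y[best], sigma_deg = cand$sigma[best],
    amplitude = a, baseline = mean(ts) - a * mean(pred[, best]),
    r2 = r2[best], low_r2 = r2[best] < 1e-6
  )
}

#' Estimate HRF delay parameters with spatial parameters fixed
#'
#' Grid search over the time-to-peak and time-to-undershoot of the
#' difference-of-gamma HRF, holding the coarse spatial fit fixed and profiling
#' amplitude and baseline at each candidate.
#'
#' @param ts voxel time series.
#' @param coarse_fit result of [coarse_grid_fit()] (or any list with
#'   `x_deg`, `y_deg`, `sigma_deg`).
#' @param movie full-resolution [stimulus_movie].
#' @param peak_bounds,undershoot_bounds search bounds in seconds (defaults
#'   c(4, 9) and c(10, 20)).
#' @param peak_step,undershoot_step grid steps in seconds (defaults 0.5, 1).
#' @param mm internal: precomputed flattened movie (shared by [fit_prf()]).
#' @return list with `hrf_peak_s`, `hrf_undershoot_s`, `r2`, and
#'   `identifiable` (FALSE when the series carries no stimulus-locked
#'   variance, in which case the default delays 6 and 16 s are returned).
#' @export
fit_hrf_delays <- function(ts, coarse_fit, movie, peak_bounds = c(4, 9),
                           undershoot_bounds = c(10, 20), peak_step = 0.5,
                           undershoot_step = 1, mm = NULL) {
  if (peak_bounds[1] >= peak_bounds[2] ||
      undershoot_bounds[1] >= undershoot_bounds[2]) {
    stop("inverted HRF delay bounds")
  }
  if (is.null(mm)) mm <- movie_matrix(movie)
  drive <- prf_drive(mm, coarse_fit$x_deg, coarse_fit$y_deg,
                     coarse_fit$sigma_deg)
  peaks <- seq(peak_bounds[1], peak_bounds[2], by = peak_step)
  unders <- seq(undershoot_bounds[1], undershoot_bounds[2],
                by = undershoot_step)
  best <- list(hrf_peak_s = 6, hrf_undershoot_s = 16, r2 = -Inf)
  for (p in peaks) {
    for (u in unders) {
      pred <- convolve_hrf(drive, hrf_kernel(movie$tr_s, p, u))
      fit <- profile_linear(pred, ts)
      if (fit$r2 > best$r2) {
        best <- list(hrf_peak_s = p, hrf_undershoot_s = u, r2 = fit$r2)
      }
    }
  }
  if (!is.finite(best$r2) || best$r2 < 1e-6) {
    return(list(hrf_peak_s = 6, hrf_undershoot_s = 16, r2 = max(best$r2, 0),
                identifiable = FALSE))
  }
  best$identifiable <- TRUE
  best
}

# RSS objective over (x, y, sigma, peak, undershoot), amplitude/baseline
# profiled. Used by refine_fit.
prf_objective <- function(par, mm, tr_s, ts) {
  sigma <- par[3]
  if (sigma <= 0) return(sum((ts - mean(ts))^2) * 2)
  drive <- prf_drive(mm, par[1], par[2], sigma)
  pred <- convolve_hrf(drive, hrf_kernel(tr_s, par[4], par[5]))
  profile_linear(pred, ts)$rss
}

#' Refine a pRF fit by bounded quasi-Newton minimization
#'
#' Local minimization of the residual sum of squares over center, size, and
#' the two HRF delays against the full-resolution stimulus, starting from the
#' coarse/HRF-stage seed. Amplitude and baseline remain profiled. The result
#' never has lower r2 than the seed: if the optimizer fails to improve, the
#' seed-stage parameters are returned flagged as unconverged.
#'
#' @param ts voxel time series.
#' @param movie full-resolution [stimulus_movie].
#' @param seed_params list with `x_deg`, `y_deg`, `sigma_deg`,
#'   `hrf_peak_s`, `hrf_undershoot_s` (e.g. merged coarse + HRF fits).
#' @param bounds list of lower/upper bounds; defaults: centers within
#'   +/-1.25 * extent, sigma in [0.05, 2 * extent], peak in [4, 9],
#'   undershoot in [10, 20].
#' @param maxit maximum optimizer iterations (default 500).
#' @param mm internal: precomputed flattened movie (shared by [fit_prf()]).
#' @return list of class `prf_fit`: `x_deg`, `y_deg`, `sigma_deg`,
#'   `hrf_peak_s`, `hrf_undershoot_s`, `amplitude`, `baseline`, `r2`,
#'   `angle_deg`, `ecc_deg`, `converged`.
#' @export
refine_fit <- function(ts, movie, seed_params, bounds = NULL, maxit = 500,
                       mm = NULL) {
  if (is.null(mm)) mm <- movie_matrix(movie)
  ext <- movie$extent_deg
  if (is.null(bounds)) {
    bounds <- list(
      lower = c(-1.25 * ext, -1.25 * ext, 0.05, 4, 10),
      upper = c(1.25 * ext, 1.25 * ext, 2 * ext, 9, 20)
    )
  }
  p0 <- c(seed_params$x_deg, seed_params$y_deg, seed_params$sigma_deg,
          seed_params$hrf_peak_s, seed_params$hrf_undershoot_s)
  p0 <- pmin(pmax(p0, bounds$lower), bounds$upper)
  seed_rss <- prf_objective(p0, mm, movie$tr_s, ts)

  run_opt <- function(par) {
    tryCatch(
      stats::optim(par, prf_objective, mm = mm, tr_s = movie$tr_s, ts = ts,
                   method = "L-BFGS-B", lower = bounds$lower,
                   upper = bounds$upper,
                   control = list(maxit = maxit, factr = 1e1,
                                  ndeps = rep(1e-5, 5))),
      error = function(e) NULL
    )
  }
  opt <- run_opt(p0)
  if (!is.null(opt)) {
    # polish: restart from the first solution to escape premature stops of
    # the finite-difference quasi-Newton search
    opt2 <- run_opt(opt$par)
    if (!is.null(opt2) && opt2$value <= opt$value) opt <- opt2
  }
  use_seed <- is.null(opt) || !is.finite(opt$value) || opt$value > seed_rss
  par <- if (use_seed) p0 else opt$par
  converged <- !use_seed && opt$convergence == 0

  drive <- prf_drive(mm, par[1], par[2], par[3])
  pred <- convolve_hrf(drive, hrf_kernel(movie$tr_s, par[4], par[5]))
  lin <- profile_linear(pred, ts)
  pol <- cart2polar(par[1], par[2])
  structure(list(
    x_deg = par[1], y_deg = par[2], sigma_deg = par[3],
    hrf_peak_s = par[4], hrf_undershoot_s = par[5],
    amplitude = lin$amplitude, baseline = lin$baseline, r2 = lin$r2,
    angle_deg = pol$angle_deg, ecc_deg = pol$ecc_deg,
    converged = converged
  ), class = "prf_fit")
}

#' Fit the pRF model to every voxel of a mapping run
#'
#' Runs the full coarse-grid, HRF-delay, and refinement chain per voxel.
#'
#' @param bold voxel x TR matrix of (detrended, z-scored) BOLD.
#' @param movie full-resolution [stimulus_movie] of the mapping stimulus.
#' @param grid_spec coarse search grid (default [default_grid_spec()] at the
#'   movie's extent).
#' @param downsample_factor spatial downsampling of the effective stimulus
#'   for the coarse stage (default 0.05).
#' @param fit_hrf estimate HRF delays per voxel (default TRUE).
#' @param refine run the quasi-Newton refinement (default TRUE).
#' @return data.frame with one row per voxel: `voxel`, `x_deg`, `y_deg`,
#'   `sigma_deg`, `angle_deg`, `ecc_deg`, `hrf_peak_s`, `hrf_undershoot_s`,
#'   `baseline`, `amplitude`, `r2`, `converged`.
#' @examples
#' \donttest{
#' mov <- make_bar_aperture_sequence(grid_size = 48)
#' vox <- sample_ground_truth_voxels(3, seed = 1, extent_deg = 10)
#' bold <- simulate_retinotopy_run(mov, vox)
#' fits <- fit_prf(bold, mov)
#' }
#' @export
fit_prf <- function(bold, movie, grid_spec = NULL, downsample_factor = 0.05,
                    fit_hrf = TRUE, refine = TRUE) {
  stopifnot(is.matrix(bold), ncol(bold) == dim(movie$frames)[1])
  if (is.null(grid_spec)) grid_spec <- default_grid_spec(movie$extent_deg)
  coarse_movie <- downsample_movie(movie, downsample_factor)
  grid_pred <- build_grid_predictions(coarse_movie, grid_spec)
  mm_full <- movie_matrix(movie)

  rows <- vector("list", nrow(bold))
  for (v in seq_len(nrow(bold))) {
    ts <- bold[v, ]
    cg <- coarse_grid_fit(ts, coarse_movie, grid_spec, grid_pred = grid_pred)
    hr <- if (fit_hrf) {
      fit_hrf_delays(ts, cg, movie, mm = mm_full)
    } else {
      list(hrf_peak_s = 6, hrf_undershoot_s = 16)
    }
    seedp <- list(x_deg = cg$x_deg, y_deg = cg$y_deg, sigma_deg = cg$sigma_deg,
                  hrf_peak_s = hr$hrf_peak_s,
                  hrf_undershoot_s = hr$hrf_undershoot_s)
    fit <- if (refine) {
      refine_fit(ts, movie, seedp, mm = mm_full)
    } else {
      drive <- prf_drive(mm_full, seedp$x_deg, seedp$y_deg, seedp$sigma_deg)
      pred <- convolve_hrf(drive, hrf_kernel(movie$tr_s, seedp$hrf_peak_s,
                                             seedp$hrf_undershoot_s))
      lin <- profile_linear(pred, ts)
      pol <- cart2polar(seedp$x_deg, seedp$y_deg)
      c(seedp, list(amplitude = lin$amplitude, baseline = lin$baseline,
                    r2 = lin$r2, angle_deg = pol$angle_deg,
                    ecc_deg = pol$ecc_deg, converged = TRUE))
    }
    rows[[v]] <- data.frame(
      voxel = v, x_deg = fit$x_deg, y_deg = fit$y_deg,
      sigma_deg = fit$sigma_deg, angle_deg = fit$angle_deg,
      ecc_deg = fit$ecc_deg, hrf_peak_s = fit$hrf_peak_s,
      hrf_undershoot_s = fit$hrf_undershoot_s, baseline = fit$baseline,
      amplitude = fit$amplitude, r2 = fit$r2, converged = fit$converged
    )
  }
  do.call(rbind, rows)
}

#' Select region-of-interest voxels by variance explained
#'
#' @param fits data.frame from [fit_prf()] (needs an `r2` column).
#' @param r2_threshold inclusive threshold on variance explained
#'   (default 0.1).
#' @param fallback optional integer index set returned (with a warning) when
#'   no voxel passes threshold, mirroring an anatomically defined fallback
#'   region when the functional model fails.
#' @return integer vector of voxel indices, in input order.
#' @export
select_roi <- function(fits, r2_threshold = 0.1, fallback = NULL) {
  idx <- which(fits$r2 >= r2_threshold)
  if (length(idx) == 0 && !is.null(fallback)) {
    warning("no voxel reached the r2 threshold; using the supplied fallback set")
    return(as.integer(fallback))
  }
  idx
}
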