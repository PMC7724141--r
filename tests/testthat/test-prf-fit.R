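test_that("predict_bold is consistent with the simulator and linear in gain", {
  mov <- small_movie()
  p <- list(x_deg = 5, y_deg = -2, sigma_deg = 1.5, hrf_peak_s = 6,
            hrf_undershoot_s = 16, baseline = 0.5, amplitude = 2)
  # zero amplitude -> constant baseline
  p0 <- p
  p0$amplitude <- 0
  expect_true(all(predict_bold(p0, mov) == 0.5))
  expect_error(predict_bold(list(x_deg = 0, y_deg = 0, sigma_deg = -1), mov),
               "sigma")
  # shared forward model: prediction equals the noiseless simulation
  vox <- data.frame(x_deg = 5, y_deg = -2, sigma_deg = 1.5, hrf_peak_s = 6,
                    hrf_undershoot_s = 16, baseline = 0.5, amplitude = 2,
                    noise_sd = 0)
  expect_equal(predict_bold(p, mov),
               as.vector(simulate_retinotopy_run(mov, vox)), tolerance = 1e-12)
  # doubling amplitude doubles the demeaned prediction
  p2 <- p
  p2$amplitude <- 4
  y1 <- predict_bold(p, mov)
  y2 <- predict_bold(p2, mov)
  expect_equal(y2 - mean(y2), 2 * (y1 - mean(y1)), tolerance = 1e-10)
})

test_that("coarse grid search returns the exhaustive-evaluation optimum", {
  mov <- small_movie()
  coarse <- downsample_movie(mov, 0.25)
  grid <- default_grid_spec(16, step_deg = 2)
  vox <- data.frame(x_deg = 5, y_deg = 0, sigma_deg = 1, hrf_peak_s = 6,
                    hrf_undershoot_s = 16, baseline = 0, amplitude = 1,
                    noise_sd = 0)
  ts <- as.vector(simulate_retinotopy_run(mov, vox))
  fit <- coarse_grid_fit(ts, coarse, grid)
  # within one grid step of the true center
  expect_lte(abs(fit$x_deg - 5), 2)
  expect_lte(abs(fit$y_deg - 0), 2)
  expect_false(fit$low_r2)

  # oracle: brute-force loop over every candidate must agree on the winner
  gp <- scwm:::build_grid_predictions(coarse, grid)
  Q <- scwm:::trend_basis(length(ts))
  r2 <- apply(gp$pred, 2, function(pr) {
    scwm:::profile_linear(pr, ts, Q)$r2
  })
  best <- which.max(r2)
  expect_equal(fit$x_deg, gp$candidates$x[best])
  expect_equal(fit$y_deg, gp$candidates$y[best])
  expect_equal(fit$sigma_deg, gp$candidates$sigma[best])
  expect_equal(fit$r2, r2[best], tolerance = 1e-10)

  # constant series: flagged, amplitude zero
  flat <- coarse_grid_fit(rep(1, 96), coarse, grid)
  expect_true(flat$low_r2)
  expect_equal(flat$amplitude, 0)
  expect_error(coarse_grid_fit(ts, coarse, list(x = numeric(0),
                                                y = numeric(0),
                                                sigma = numeric(0))),
               "empty")
})

test_that("HRF delay estimation recovers and orders the true delays", {
  mov <- small_movie()
  mk <- function(peak) {
    vox <- data.frame(x_deg = 5, y_deg = 0, sigma_deg = 1, hrf_peak_s = peak,
                      hrf_undershoot_s = 16, baseline = 0, amplitude = 1,
                      noise_sd = 0)
    as.vector(simulate_retinotopy_run(mov, vox))
  }
  coarse <- list(x_deg = 5, y_deg = 0, sigma_deg = 1)
  f6 <- fit_hrf_delays(mk(6), coarse, mov)
  expect_true(f6$identifiable)
  expect_lte(abs(f6$hrf_peak_s - 6), 0.5)
  # ordering preserved for 5 s vs 7 s
  f5 <- fit_hrf_delays(mk(5), coarse, mov)
  f7 <- fit_hrf_delays(mk(7), coarse, mov)
  expect_lt(f5$hrf_peak_s, f7$hrf_peak_s)
  # flat data: unidentifiable, default delays returned with flag
  ff <- fit_hrf_delays(rep(0, 96), coarse, mov)
  expect_false(ff$identifiable)
  expect_equal(ff$hrf_peak_s, 6)
  expect_equal(ff$hrf_undershoot_s, 16)
  expect_error(fit_hrf_delays(mk(6), coarse, mov, peak_bounds = c(9, 4)),
               "inverted")
})

test_that("refinement recovers noiseless parameters and never degrades r2", {
  mov <- small_movie()
  vox <- data.frame(x_deg = -6.3, y_deg = 4.1, sigma_deg = 1.7,
                    hrf_peak_s = 5.5, hrf_undershoot_s = 14, baseline = 0,
                    amplitude = 1, noise_sd = 0)
  ts <- detrend_zscore(simulate_retinotopy_run(mov, vox), 96)[1, ]
  seedp <- list(x_deg = -6, y_deg = 4, sigma_deg = 2, hrf_peak_s = 6,
                hrf_undershoot_s = 16)
  fit <- refine_fit(ts, mov, seedp)
  expect_lt(sqrt((fit$x_deg + 6.3)^2 + (fit$y_deg - 4.1)^2), 0.1)
  expect_lt(abs(fit$sigma_deg - 1.7) / 1.7, 0.05)
  expect_gte(fit$r2, 0.99)
  # fixed point: reseeding from the optimum changes nothing material
  fit2 <- refine_fit(ts, mov, fit)
  expect_gte(fit2$r2, fit$r2 - 1e-12)
  expect_lt(abs(fit2$x_deg - fit$x_deg), 1e-3)
  # monotone refinement on noisy data over replicates
  set.seed(11)
  for (i in 1:5) {
    noisy <- ts + rnorm(96, 0, 1)
    cg <- coarse_grid_fit(noisy, downsample_movie(mov, 0.25))
    sfit <- list(x_deg = cg$x_deg, y_deg = cg$y_deg, sigma_deg = cg$sigma_deg,
                 hrf_peak_s = 6, hrf_undershoot_s = 16)
    seed_r2 <- scwm:::profile_linear(
      predict_bold(sfit, mov) , noisy)$r2
    expect_gte(refine_fit(noisy, mov, sfit)$r2, seed_r2 - 1e-10)
  }
})

test_that("ROI selection applies an inclusive threshold with fallback", {
  fits <- data.frame(r2 = c(0.05, 0.1, 0.9))
  expect_equal(select_roi(fits, 0.1), c(2L, 3L))
  expect_equal(select_roi(fits, 0), 1:3)
  expect_equal(select_roi(fits, 1.01), integer(0))
  expect_warning(out <- select_roi(fits, 1.01, fallback = 1:3),
                 "fallback")
  expect_equal(out, 1:3)
})
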