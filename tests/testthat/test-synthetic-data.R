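test_that("ground-truth voxel sampling respects hemifield, scaling, and seed", {
  expect_equal(nrow(sample_ground_truth_voxels(0)), 0)
  # no slope, no noise: all sigmas at the intercept
  v0 <- sample_ground_truth_voxels(50, size_slope = 0, size_noise_sd = 0,
                                   size_intercept = 0.7, seed = 1)
  expect_true(all(v0$sigma_deg == 0.7))
  vr <- sample_ground_truth_voxels(200, hemifield = "right", seed = 2)
  expect_true(all(vr$x_deg > 0))
  vl <- sample_ground_truth_voxels(200, hemifield = "left", seed = 3)
  expect_true(all(vl$x_deg < 0))
  # size-eccentricity correlation recomputed from the generated values
  v <- sample_ground_truth_voxels(500, size_slope = 0.2, seed = 4)
  expect_gt(cor(v$sigma_deg, v$ecc_deg), 0.5)
  # determinism
  expect_identical(sample_ground_truth_voxels(20, seed = 5),
                   sample_ground_truth_voxels(20, seed = 5))
})

test_that("location transformations implement the mirror geometry", {
  expect_equal(apply_transformation(30, 10, "mirror_h")$angle_deg, 330)
  expect_equal(apply_transformation(30, 10, "mirror_v")$angle_deg, 150)
  expect_equal(apply_transformation(30, 10, "mirror_both")$angle_deg, 210)
  expect_equal(apply_transformation(30, 10, "same")$angle_deg, 30)
  expect_error(apply_transformation(30, 10, "rotate"), "unknown condition")

  grid <- 0:359
  for (cond in c("mirror_h", "mirror_v", "mirror_both")) {
    # involution: applying any mirror twice returns the input
    once <- apply_transformation(grid, 10, cond)$angle_deg
    twice <- apply_transformation(once, 10, cond)$angle_deg
    expect_equal(twice, grid)
  }
  # mirror_both = mirror_h composed with mirror_v, on the whole grid
  hv <- apply_transformation(
    apply_transformation(grid, 10, "mirror_v")$angle_deg, 10, "mirror_h")
  expect_equal(hv$angle_deg,
               apply_transformation(grid, 10, "mirror_both")$angle_deg)
  # eccentricity is never changed
  expect_equal(apply_transformation(77, 9.4, "mirror_v")$ecc_deg, 9.4)
})

test_that("trial schedules are counterbalanced and correctly timed", {
  expect_error(make_wm_trial_schedule(3), "even")
  expect_error(make_wm_trial_schedule(0), "even")
  sched <- make_wm_trial_schedule(2, seed = 1)
  expect_equal(nrow(sched), 32)
  expect_equal(as.vector(table(sched$condition)), rep(8L, 4))
  for (r in 1:2) {
    run <- sched[sched$run_id == r, ]
    expect_equal(nrow(run), 16)
    expect_equal(as.vector(table(run$bin_index)), rep(2L, 8))
  }
  # each (condition, bin) combination exactly once per run pair
  expect_true(all(table(sched$condition, sched$bin_index) == 1))
  # angles within jitter of bin centers; eccentricities in [9, 11]
  expect_true(all(circ_dist(sched$visual_angle_deg, sched$bin_angle_deg) <= 10))
  expect_true(all(sched$visual_ecc_deg >= 9 & sched$visual_ecc_deg <= 11))
  expect_true(all(sched$mgs_ecc_deg >= 9 & sched$mgs_ecc_deg <= 11))
  # zero jitter puts targets exactly at bin centers
  s0 <- make_wm_trial_schedule(2, jitter_deg = 0, seed = 2)
  expect_equal(s0$visual_angle_deg, s0$bin_angle_deg)
  # same-condition trials have colocated visual and MGS targets
  same <- sched[sched$condition == "same", ]
  expect_equal(same$mgs_angle_deg, same$visual_angle_deg)
  # mgs location equals the transformation for every trial
  tr <- apply_transformation(sched$visual_angle_deg, sched$visual_ecc_deg,
                             sched$condition)
  expect_equal(sched$mgs_angle_deg, tr$angle_deg)
  # event grid: trials are 22.5 s apart, delay is 10.5 s
  expect_equal(diff(sched$stim_onset_s[sched$run_id == 1]), rep(22.5, 15))
  expect_equal(sched$cue_onset_s - sched$delay_onset_s, rep(10.5, 32))
  # larger sessions stay balanced
  s6 <- make_wm_trial_schedule(6, seed = 3)
  expect_true(all(table(s6$condition) == 24))
  expect_true(all(table(s6$run_id, s6$bin_index) == 2))
})

test_that("trial tables round-trip through TSV", {
  sched <- make_wm_trial_schedule(2, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(sched, path)
  back <- read_trial_table(path)
  expect_equal(back$condition, sched$condition)
  expect_equal(back$visual_angle_deg, sched$visual_angle_deg,
               tolerance = 1e-12)
})

test_that("retinotopy simulation obeys baseline, determinism, and linearity", {
  mov <- small_movie()
  vox <- sample_ground_truth_voxels(3, seed = 1)
  # zero movie -> constant at baseline
  zero_mov <- mov
  zero_mov$frames[] <- 0
  vb <- vox
  vb$baseline <- 2.5
  bold <- simulate_retinotopy_run(zero_mov, vb)
  expect_true(all(bold == 2.5))
  # determinism with a seed; noiseless runs need no seed
  v_noisy <- vox
  v_noisy$noise_sd <- 0.5
  expect_identical(simulate_retinotopy_run(mov, v_noisy, seed = 3),
                   simulate_retinotopy_run(mov, v_noisy, seed = 3))
  # linear in amplitude, shift-equivariant in baseline
  b1 <- simulate_retinotopy_run(mov, vox)
  v2 <- vox
  v2$amplitude <- 2 * vox$amplitude
  v2$baseline <- vox$baseline + 1
  b2 <- simulate_retinotopy_run(mov, v2)
  expect_equal(b2, 2 * b1 + 1, tolerance = 1e-12)
})

test_that("a voxel's response peaks when the bar crosses its receptive field", {
  mov <- make_bar_aperture_sequence(sweep_order = "L2R", grid_size = 64)
  vox <- data.frame(x_deg = 5, y_deg = 0, sigma_deg = 1, angle_deg = 0,
                    ecc_deg = 5, hrf_peak_s = 6, hrf_undershoot_s = 16,
                    baseline = 0, amplitude = 1, noise_sd = 0)
  bold <- simulate_retinotopy_run(mov, vox)[1, ]
  # analytic: bar centers hit x = 5 at sweep step ceil((5+16)/1.6) ~ 13-14;
  # add the HRF lag (peak 6 s = 4 TRs) after the 8 blank TRs
  centers <- -16 + (1:20 - 0.5) / 20 * 32
  drive_peak_tr <- 8 + which.min(abs(centers - 5))
  lag_tr <- 4
  expect_lt(abs(which.max(bold) - (drive_peak_tr + lag_tr)), 2.5)
})
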