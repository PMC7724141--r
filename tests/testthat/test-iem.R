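test_that("channel basis is a unimodal raised cosine partition", {
  expect_error(make_channel_basis(2), "n_channels")
  b <- make_channel_basis(9)
  expect_equal(b$centers_deg, seq(0, 320, by = 40))
  fb <- eval_channel_basis(b, 0:359)
  # each channel peaks at its own center and vanishes opposite it
  for (k in 1:9) {
    expect_equal(fb[b$centers_deg[k] + 1, k], 1)
    expect_lt(fb[(b$centers_deg[k] + 180) %% 360 + 1, k], 1e-12)
  }
  # partition: channels sum to n/2 everywhere
  expect_lt(max(abs(rowSums(fb) - 4.5)), 1e-12)
})

test_that("delay averaging selects the last four in-delay TRs", {
  sched <- make_wm_trial_schedule(2, seed = 1)
  n_tr <- 15 * 16
  # constant series: every trial response equals the constant
  bold <- matrix(3.7, 2, 2 * n_tr)
  tr <- delay_window_average(bold, sched, 1.5, n_tr)
  expect_true(all(tr$responses == 3.7))
  expect_equal(dim(tr$responses), c(32, 2))

  # delay = 10.5 s = 7 TRs; the window is TRs 4-7 of the delay (1-based).
  # An impulse in delay TR 1 contributes nothing; one in delay TR 4
  # contributes 1/4.
  bold2 <- matrix(0, 1, 2 * n_tr)
  k <- which(sched$run_id == 1 & sched$trial == 3)
  first_delay_tr <- floor(sched$delay_onset_s[k] / 1.5) + 1
  bold2[1, first_delay_tr] <- 100            # impulse in delay TR 1
  tr2 <- delay_window_average(bold2, sched, 1.5, n_tr)
  expect_equal(tr2$responses[k, 1], 0)
  bold2[1, first_delay_tr + 3] <- 8          # delay TR 4: first in window
  tr3 <- delay_window_average(bold2, sched, 1.5, n_tr)
  expect_equal(tr3$responses[k, 1], 2)
  # a delay shorter than the window is rejected
  bad <- sched
  bad$cue_onset_s <- bad$delay_onset_s + 3
  expect_error(delay_window_average(bold, bad, 1.5, n_tr), "fewer than")
})

test_that("twofold combination halves trials within condition x bin cells", {
  fx <- channel_model_fixture(n_voxels = 12, n_runs = 4, seed = 2)
  comb <- twofold_combine(fx$resp, seed = 5)
  expect_equal(nrow(comb$responses), nrow(fx$B) / 2)
  # bin x condition proportions unchanged
  expect_equal(table(comb$trials$condition, comb$trials$bin_index) * 2,
               table(fx$trials$condition, fx$trials$bin_index))
  # pairing respects cells: combined labels stay within the bin's jitter span
  expect_true(all(circ_dist(comb$trials$visual_angle_deg,
                            comb$trials$bin_angle_deg) <= 10 + 1e-9))
  # two identical rows in a cell average to themselves
  dup <- fx$resp
  cell <- which(dup$trials$condition == "same" & dup$trials$bin_index == 1)
  dup$responses[cell[2], ] <- dup$responses[cell[1], ]
  comb_dup <- twofold_combine(dup, seed = 3)
  dup_row <- which(comb_dup$trials$condition == "same" &
                     comb_dup$trials$bin_index == 1)
  expect_equal(comb_dup$responses[dup_row, ], dup$responses[cell[1], ],
               tolerance = 1e-12)
  # odd cells are rejected unless explicitly allowed
  odd <- fx$resp
  odd$responses <- odd$responses[-1, ]
  odd$trials <- odd$trials[-1, ]
  expect_error(twofold_combine(odd, seed = 1), "odd trial count")
  comb_odd <- twofold_combine(odd, seed = 1, allow_odd = TRUE)
  expect_equal(nrow(comb_odd$responses), (nrow(fx$B) - 2) / 2 + 1)
  # determinism
  expect_equal(twofold_combine(fx$resp, seed = 9),
               twofold_combine(fx$resp, seed = 9))
})

test_that("weight estimation is exact for raised-cosine tuned populations", {
  fx <- channel_model_fixture(n_voxels = 25, n_runs = 2, seed = 3)
  C <- eval_channel_basis(fx$basis, fx$trials$mgs_angle_deg)
  W <- estimate_weights(fx$B, C)
  expect_lt(max(abs(W - fx$W_true)) / max(abs(fx$W_true)), 1e-8)
  # zero data give zero weights
  expect_true(all(estimate_weights(matrix(0, 32, 25), C) == 0))
  expect_error(estimate_weights(fx$B[1:10, ], C), "same number of trial rows")
  # a design with fewer than 3 distinct angles cannot span the basis family
  C_bad <- eval_channel_basis(fx$basis, rep(c(0, 90), 8))
  expect_error(estimate_weights(fx$B[1:16, ], C_bad), "rank")
})

test_that("inversion round-trips channel coefficients and peak locations", {
  fx <- channel_model_fixture(n_voxels = 25, n_runs = 2, seed = 4)
  C <- eval_channel_basis(fx$basis, fx$trials$mgs_angle_deg)
  W <- estimate_weights(fx$B, C)
  rec <- invert_and_reconstruct(fx$B, W, fx$basis)
  # noiseless generative data: coefficients recovered to machine precision
  expect_lt(max(abs(rec$coef - C)), 1e-9)
  # every reconstruction peaks at its generating angle (1 deg grid)
  for (t in seq_len(8)) {
    pk <- scwm:::profile_peak(rec$theta_deg, rec$profiles[t, ])
    expect_lte(circ_dist(pk, fx$trials$mgs_angle_deg[t]), 0.5)
  }
  # zero test data give a flat zero reconstruction
  rec0 <- invert_and_reconstruct(matrix(0, 3, 25), W, fx$basis)
  expect_true(all(abs(rec0$profiles) < 1e-12))
  expect_error(invert_and_reconstruct(fx$B, matrix(0, 25, 9), fx$basis),
               "zero")
  expect_error(invert_and_reconstruct(fx$B[, 1:10], W, fx$basis), "columns")

  # oracle: pseudoinverse peak equals an explicit normal-equation solve
  set.seed(5)
  B_noisy <- fx$B + matrix(rnorm(length(fx$B), 0, 0.2), nrow(fx$B))
  rec_n <- invert_and_reconstruct(B_noisy, W, fx$basis)
  sv <- svd(W)
  keep <- sv$d > max(sv$d) * 1e-8
  W_pinv <- sv$v[, keep] %*% diag(1 / sv$d[keep]) %*% t(sv$u[, keep])
  C_oracle <- B_noisy %*% t(W_pinv)
  expect_equal(unname(rec_n$coef), unname(C_oracle), tolerance = 1e-8)
})

test_that("alignment recenters profiles exactly and is rotation-equivariant", {
  fx <- channel_model_fixture(n_voxels = 25, n_runs = 2, seed = 6)
  C <- eval_channel_basis(fx$basis, fx$trials$mgs_angle_deg)
  W <- estimate_weights(fx$B, C)
  rec <- invert_and_reconstruct(fx$B, W, fx$basis)
  refs <- fx$trials$mgs_angle_deg
  expect_error(align_and_average(rec, refs[-1]), "one reference angle")

  # single trial with reference 0: profile unchanged
  one <- invert_and_reconstruct(fx$B[1, , drop = FALSE], W, fx$basis)
  al1 <- align_and_average(one, 0)
  expect_equal(al1$values, one$profiles[1, ], tolerance = 1e-12)

  # profiles peaked at their references average to a peak at 0
  al <- align_and_average(rec, refs)
  expect_lte(circ_dist(al$peak_deg, 0), 0.5)

  # shifting all labels and references by +40 deg leaves the result intact
  B_rot <- eval_channel_basis(fx$basis, refs + 40) %*% t(fx$W_true)
  W_rot <- estimate_weights(B_rot, eval_channel_basis(fx$basis, refs + 40))
  rec_rot <- invert_and_reconstruct(B_rot, W_rot, fx$basis)
  al_rot <- align_and_average(rec_rot, refs + 40)
  expect_lt(max(abs(al_rot$values - al$values)), 1e-10)
})

test_that("voxel tuning curves from weights recover preferred angles", {
  b <- make_channel_basis()
  # indicator weight row peaks at that channel's center
  W <- diag(9)
  for (k in c(1, 4, 9)) {
    tun <- voxel_tuning_from_weights(W, b, k)
    expect_equal(tun$peak_deg, b$centers_deg[k])
    expect_false(tun$flat)
  }
  # uniform weights: flat curve, flagged
  Wu <- matrix(1, 2, 9)
  tun_u <- voxel_tuning_from_weights(Wu, b, 1)
  expect_true(tun_u$flat)
  expect_true(is.na(tun_u$peak_deg))
  # recovery at moderate noise: preferred angle 137 deg within 20 deg
  vox <- sample_ground_truth_voxels(40, seed = 7)
  vox$angle_deg[1] <- 137
  sched <- make_wm_trial_schedule(4, seed = 8)
  ds <- simulate_wm_dataset(sched, vox, encoded_reference = "visual",
                            snr = 2, seed = 9)
  same <- ds$trials$condition == "same"
  W_fit <- estimate_weights(ds$responses[same, ],
                            eval_channel_basis(b, ds$trials$visual_angle_deg[same]))
  tun <- voxel_tuning_from_weights(W_fit, b, 1)
  expect_lte(circ_dist(tun$peak_deg, 137), 20)
})

test_that("training uses only same-condition rows (training purity)", {
  fx <- channel_model_fixture(n_voxels = 20, n_runs = 4, seed = 10)
  res <- run_iem(fx$resp, "mgs", combine = FALSE)
  # permute the transformed-condition rows: W must be bit-identical
  perm <- fx$resp
  idx <- which(perm$trials$condition != "same")
  set.seed(1)
  shuf <- sample(idx)
  perm$responses[idx, ] <- perm$responses[shuf, ]
  perm$trials[idx, ] <- perm$trials[shuf, ]
  res2 <- run_iem(perm, "mgs", combine = FALSE)
  expect_identical(res$W, res2$W)
})

test_that("bootstrap over re-pairings is deterministic and stable", {
  fx <- channel_model_fixture(n_voxels = 20, n_runs = 4, seed = 11)
  expect_error(bootstrap_reconstruction(fx$resp, n_iter = 0), "n_iter")
  # n_iter = 1 equals a single pass at the derived seed
  b1 <- bootstrap_reconstruction(fx$resp, "mgs", n_iter = 1, seed = 20)
  single <- run_iem(fx$resp, "mgs", seed = 22)
  expect_equal(b1$fidelity$modified,
               fidelity_modified(single$aligned, 0))
  # noiseless generative data: every re-pairing peaks at 0 after alignment
  bs <- bootstrap_reconstruction(fx$resp, "mgs", n_iter = 25, seed = 30)
  expect_true(all(circ_dist(bs$fidelity$peak_deg, 0) <= 1))
  expect_true(all(bs$fidelity$modified > 0))
})
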