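# Shared fixtures, built in code. Small stimulus movies keep the forward
# model cheap; the full-size defaults are exercised in the acceptance tests.

small_movie <- function(grid_size = 48, ...) {
  make_bar_aperture_sequence(grid_size = grid_size, ...)
}

# Trial-response fixture generated exactly from the channel model:
# B = C %*% t(W_true) with W_true drawn from the raised-cosine tuning family.
channel_model_fixture <- function(n_voxels = 30, n_runs = 4, seed = 1,
                                  basis = make_channel_basis()) {
  vox <- sample_ground_truth_voxels(n_voxels, seed = seed)
  trials <- make_wm_trial_schedule(n_runs, seed = seed + 1)
  W_true <- eval_channel_basis(basis, vox$angle_deg)  # voxels x channels
  C_all <- eval_channel_basis(basis, trials$mgs_angle_deg)
  B <- C_all %*% t(W_true)
  list(voxels = vox, trials = trials, W_true = W_true, B = B,
       basis = basis,
       resp = structure(list(responses = B, trials = trials),
                        class = "trial_responses"))
}

# Brute-force drive oracle: explicit per-pixel loop, independent of the
# package's (separable / matrix) forward-model code path.
brute_force_drive <- function(movie, x, y, sigma) {
  d <- dim(movie$frames)
  ys <- -movie$extent_deg + (seq_len(d[2]) - 0.5) * 2 * movie$extent_deg / d[2]
  xs <- -movie$extent_deg + (seq_len(d[3]) - 0.5) * 2 * movie$extent_deg / d[3]
  g <- outer(ys, xs, function(yy, xx) {
    exp(-((xx - x)^2 + (yy - y)^2) / (2 * sigma^2))
  })
  g <- g / sum(g)
  vapply(seq_len(d[1]), function(t) sum(movie$frames[t, , ] * g), numeric(1))
}
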