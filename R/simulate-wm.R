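#' Simulate working-memory task responses with known spatial tuning
#'
#' Generates voxel responses for a memory-guided saccade session under the
#' assumption that each voxel carries polar-angle tuning anchored at its
#' receptive-field polar angle, i.e. the retinotopic organization measured at
#' mapping carries over to the memory delay. The tuning curve is the same
#' raised-cosine family as the encoding-model basis, so in the noiseless limit
#' the encoding model's generative assumption holds exactly.
#'
#' In `"trialwise"` mode the result is a trials x voxels matrix of
#' delay-period responses. In `"timeseries"` mode each trial's response is
#' placed as a boxcar over the delay period, convolved with the voxel's HRF,
#' and returned as a voxel x TR matrix spanning all runs.
#'
#' @param trials trial table from [make_wm_trial_schedule()].
#' @param voxels data.frame from [sample_ground_truth_voxels()]; every voxel
#'   must have a defined polar angle (`angle_deg`).
#' @param encoded_reference which trial location drives the response:
#'   `"mgs"` (default), `"visual"`, or `"vgs"`.
#' @param tuning_power exponent applied to the raised cosine
#'   `((1 + cos(delta))/2)^tuning_power`; 1 (default) reproduces the encoding
#'   basis, larger values narrow the tuning.
#' @param snr signal-to-noise ratio: tuning amplitude divided by the noise SD
#'   (> 0; `Inf` for noiseless).
#' @param mode `"trialwise"` or `"timeseries"`.
#' @param tr_s repetition time for timeseries mode (default 1.5).
#' @param trial_s trial duration in seconds (default 22.5).
#' @param seed RNG seed (optional).
#' @return an object of class `wm_dataset`: a list with `trials`, `voxels`,
#'   `mode`, `encoded_reference`, and either `responses` (trials x voxels) or
#'   `bold` (voxels x TR) plus `tr_s` and `n_tr_per_run`.
#' @examples
#' vox <- sample_ground_truth_voxels(20, seed = 1)
#' sched <- make_wm_trial_schedule(2, seed = 2)
#' ds <- simulate_wm_dataset(sched, vox, snr = Inf, seed = 3)
#' dim(ds$responses)
#' @export
simulate_wm_dataset <- function(trials, voxels,
                                encoded_reference = c("mgs", "visual", "vgs"),
                                tuning_power = 1, snr = 2,
                                mode = c("trialwise", "timeseries"),
                                tr_s = 1.5, trial_s = 22.5, seed = NULL) {
  encoded_reference <- match.arg(encoded_reference)
  mode <- match.arg(mode)
  if (!is.numeric(snr) || snr <= 0) stop("snr must be > 0 (use Inf for noiseless)")
  stopifnot(nrow(voxels) >= 1, all(is.finite(voxels$angle_deg)))
  ref_col <- paste0(encoded_reference, "_angle_deg")
  ref_angles <- trials[[ref_col]]
  pref <- voxels$angle_deg
  amp <- voxels$amplitude
  noise_sd <- if (is.infinite(snr)) rep(0, nrow(voxels)) else amp / snr

  # trials x voxels matrix of noiseless tuned responses
  delta <- outer(ref_angles, pref, circ_diff)
  tuned <- sweep(((1 + cos(deg2rad(delta))) / 2)^tuning_power, 2, amp, `*`)

  out <- list(
    trials = trials, voxels = voxels, mode = mode,
    encoded_reference = encoded_reference, tuning_power = tuning_power,
    snr = snr
  )
  with_seed(seed, {
    if (mode == "trialwise") {
      noise <- matrix(stats::rnorm(length(tuned), 0,
                                   rep(noise_sd, each = nrow(trials))),
                      nrow(trials), nrow(voxels))
      out$responses <- tuned + noise
    } else {
      n_trial_tr <- round(trial_s / tr_s)
      run_ids <- sort(unique(trials$run_id))
      n_run_tr <- n_trial_tr * max(tapply(trials$trial, trials$run_id, length))
      n_tr <- n_run_tr * length(run_ids)
      bold <- matrix(0, nrow(voxels), n_tr)
      for (v in seq_len(nrow(voxels))) {
        hrf <- hrf_kernel(tr_s, voxels$hrf_peak_s[v], voxels$hrf_undershoot_s[v])
        for (r in seq_along(run_ids)) {
          idx <- which(trials$run_id == run_ids[r])
          drive <- numeric(n_run_tr)
          tt <- (seq_len(n_run_tr) - 1) * tr_s
          for (k in idx) {
            on <- trials$delay_onset_s[k]; off <- trials$cue_onset_s[k]
            drive[tt >= on & tt < off] <- tuned[k, v]
          }
          cols <- (r - 1) * n_run_tr + seq_len(n_run_tr)
          bold[v, cols] <- convolve_hrf(drive, hrf) + voxels$baseline[v]
        }
      }
      if (any(noise_sd > 0)) {
        bold <- bold + matrix(stats::rnorm(length(bold), 0,
                                           rep(noise_sd, n_tr)),
                              nrow(voxels), n_tr)
      }
      out$bold <- bold
      out$tr_s <- tr_s
      out$n_tr_per_run <- n_run_tr
    }
    structure(out, class = "wm_dataset")
  })
}

#' @export
print.wm_dataset <- function(x, ...) {
  cat(sprintf(
    "wm_dataset (%s): %d trials x %d voxels, encoded reference '%s', snr %s\n",
    x$mode, nrow(x$trials), nrow(x$voxels), x$encoded_reference,
    format(x$snr)
  ))
  invisible(x)
}
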