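#' Memory-guided saccade task: trial schedules and location transformations
#'
#' Each trial of the spatial working-memory task presents a peripheral visual
#' target at one of 8 polar-angle bins (22.5 to 337.5 degrees in 45 degree
#' steps, jittered), followed by a memory delay, an intervening visually
#' guided saccade (VGS) to a random location, and a memory-guided saccade
#' (MGS) to a transformation of the visual target. The four transformation
#' conditions (identity and mirrors across the horizontal, vertical, and both
#' meridians) dissociate the remembered goal from the retinally stimulated
#' location.
#'
#' @name wm_task
NULL

wm_conditions <- c("same", "mirror_h", "mirror_v", "mirror_both")

#' Transform a visual-target location into the MGS goal location
#'
#' @param angle_deg polar angle of the visual target in [0, 360).
#' @param ecc_deg eccentricity of the visual target (unchanged by every
#'   transformation).
#' @param condition one of `"same"`, `"mirror_h"` (mirror across the
#'   horizontal meridian), `"mirror_v"` (vertical meridian), `"mirror_both"`.
#' @return list with transformed `angle_deg` and `ecc_deg`.
#' @examples
#' apply_transformation(30, 10, "mirror_h")$angle_deg  # 330
#' @export
apply_transformation <- function(angle_deg, ecc_deg, condition) {
  if (!all(condition %in% wm_conditions)) {
    stop("unknown condition(s): ",
         paste(setdiff(condition, wm_conditions), collapse = ", "))
  }
  if (length(condition) == 1) condition <- rep(condition, length(angle_deg))
  out <- numeric(length(angle_deg))
  out[condition == "same"] <- angle_deg[condition == "same"]
  out[condition == "mirror_h"] <- -angle_deg[condition == "mirror_h"]
  out[condition == "mirror_v"] <- 180 - angle_deg[condition == "mirror_v"]
  out[condition == "mirror_both"] <- angle_deg[condition == "mirror_both"] + 180
  list(angle_deg = wrap_angle(out), ecc_deg = ecc_deg)
}

#' Generate a counterbalanced trial schedule for the spatial WM task
#'
#' Each run holds 16 trials of 22.5 s, sampling each of the 8 angular bins
#' exactly twice. The four transformation conditions are counterbalanced
#' across pairs of successive runs: within a pair, every (condition, bin)
#' combination occurs exactly once. Visual-target angles are jittered
#' uniformly within +/-`jitter_deg` of the bin center; eccentricities are
#' uniform in [9, 11] degrees. The VGS target is drawn independently and
#' uniformly in angle, and the MGS goal is the transformed visual target.
#'
#' Event onsets within each 22.5 s trial: stimulus at 0 s (300 ms), delay at
#' 0.3 s (10.5 s), saccade cue at 10.8 s (1.4 s for both saccades), feedback
#' at 12.2 s (500 ms), intertrial interval at 12.7 s (9.8 s).
#'
#' @param n_runs number of runs; must be even so conditions counterbalance
#'   across run pairs.
#' @param jitter_deg half-width of the uniform angular jitter (default 10).
#' @param trial_s trial duration in seconds (default 22.5).
#' @param seed RNG seed (optional).
#' @return data.frame with one row per trial: `run_id`, `trial`, `condition`,
#'   `bin_index`, `bin_angle_deg`, `visual_angle_deg`, `visual_ecc_deg`,
#'   `vgs_angle_deg`, `vgs_ecc_deg`, `mgs_angle_deg`, `mgs_ecc_deg`, and the
#'   event onsets `stim_onset_s`, `delay_onset_s`, `cue_onset_s`,
#'   `feedback_onset_s`, `iti_onset_s` (seconds from run start).
#' @examples
#' sched <- make_wm_trial_schedule(2, seed = 1)
#' table(sched$condition)  # 8 trials per condition
#' @export
make_wm_trial_schedule <- function(n_runs, jitter_deg = 10, trial_s = 22.5,
                                   seed = NULL) {
  if (n_runs < 2 || n_runs %% 2 != 0) {
    stop("n_runs must be even: the four transformation conditions are ",
         "counterbalanced across pairs of successive runs")
  }
  bin_angles <- 22.5 + 45 * (0:7)
  with_seed(seed, {
    runs <- vector("list", n_runs)
    for (pair in seq_len(n_runs / 2)) {
      # every (condition, bin) combination once per pair; per bin, split the
      # four conditions 2/2 between the two runs so each run samples each bin
      # exactly twice
      run_a <- list(); run_b <- list()
      for (b in 1:8) {
        conds <- sample(wm_conditions)
        run_a[[b]] <- data.frame(bin_index = b, condition = conds[1:2])
        run_b[[b]] <- data.frame(bin_index = b, condition = conds[3:4])
      }
      ra <- do.call(rbind, run_a); rb <- do.call(rbind, run_b)
      runs[[2 * pair - 1]] <- ra[sample(nrow(ra)), ]
      runs[[2 * pair]] <- rb[sample(nrow(rb)), ]
    }
    tab <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
      x <- runs[[r]]
      x$run_id <- r
      x$trial <- seq_len(nrow(x))
      x
    }))
    n <- nrow(tab)
    tab$bin_angle_deg <- bin_angles[tab$bin_index]
    tab$visual_angle_deg <- wrap_angle(
      tab$bin_angle_deg + stats::runif(n, -jitter_deg, jitter_deg))
    tab$visual_ecc_deg <- stats::runif(n, 9, 11)
    tab$vgs_angle_deg <- stats::runif(n, 0, 360)
    tab$vgs_ecc_deg <- stats::runif(n, 9, 11)
    mgs <- apply_transformation(tab$visual_angle_deg, tab$visual_ecc_deg,
                                tab$condition)
    tab$mgs_angle_deg <- mgs$angle_deg
    tab$mgs_ecc_deg <- mgs$ecc_deg
    t0 <- (tab$trial - 1) * trial_s
    tab$stim_onset_s <- t0
    tab$delay_onset_s <- t0 + 0.3
    tab$cue_onset_s <- t0 + 10.8
    tab$feedback_onset_s <- t0 + 12.2
    tab$iti_onset_s <- t0 + 12.7
    rownames(tab) <- NULL
    tab[, c("run_id", "trial", "condition", "bin_index", "bin_angle_deg",
            "visual_angle_deg", "visual_ecc_deg", "vgs_angle_deg",
            "vgs_ecc_deg", "mgs_angle_deg", "mgs_ecc_deg", "stim_onset_s",
            "delay_onset_s", "cue_onset_s", "feedback_onset_s", "iti_onset_s")]
  })
}

#' Read/write a trial table as tab-separated values
#'
#' @param trials data.frame from [make_wm_trial_schedule()].
#' @param path file path.
#' @return `read_trial_table` returns the trial data.frame;
#'   `write_trial_table` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
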