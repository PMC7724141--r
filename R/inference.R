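#' Subject- and group-level inference and tuning comparisons
#'
#' @name inference
NULL

#' Subject-level test: bootstrap fidelities against the permutation null
#'
#' Two-sample Kolmogorov-Smirnov test comparing the distribution of real
#' (bootstrap) fidelity values with the permutation-null distribution for one
#' subject.
#'
#' @param real_dist numeric vector of fidelities from the real data (e.g.
#'   bootstrap iterations).
#' @param null_dist numeric vector of permutation-null fidelities.
#' @return list with `statistic` (KS D), `p`, `n_real`, `n_null`.
#' @export
subject_level_test <- function(real_dist, null_dist) {
  if (length(real_dist) == 0 || length(null_dist) == 0) {
    stop("both distributions must be nonempty")
  }
  kt <- suppressWarnings(stats::ks.test(real_dist, null_dist))
  list(statistic = unname(kt$statistic), p = kt$p.value,
       n_real = length(real_dist), n_null = length(null_dist))
}

#' Group-level test: paired t test over bootstrap-stabilized subject means
#'
#' Per subject, the real and null fidelity distributions are summarized by
#' their means; a subject-level bootstrap (resampling subjects with
#' replacement, `n_boot` iterations) provides a confidence interval on the
#' group mean difference, and a paired t test across subjects compares real
#' against null. Procedure: (1) subject means of real and null fidelity;
#' (2) bootstrap distribution of the group mean difference; (3) paired
#' one-tailed t test (real > null).
#'
#' @param per_subject_real list of numeric vectors, one per subject.
#' @param per_subject_null list of numeric vectors, one per subject.
#' @param n_boot bootstrap iterations over subjects (default 1000).
#' @param seed RNG seed (optional).
#' @return list with `t`, `p` (one-tailed, real > null), `mean_diff`,
#'   `boot_ci` (2.5/97.5 percentiles of the bootstrap mean difference),
#'   `subject_real`, `subject_null`, `procedure`.
#' @export
group_level_test <- function(per_subject_real, per_subject_null,
                             n_boot = 1000, seed = NULL) {
  n_sub <- length(per_subject_real)
  if (n_sub < 2 || length(per_subject_null) != n_sub) {
    stop("need matched real/null distributions for at least 2 subjects")
  }
  real_means <- vapply(per_subject_real, mean, numeric(1))
  null_means <- vapply(per_subject_null, mean, numeric(1))
  boot_diff <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_sub, n_sub, replace = TRUE)
      mean(real_means[idx] - null_means[idx])
    }, numeric(1))
  })
  diffs <- real_means - null_means
  if (stats::sd(diffs) < 1e-12) {
    # degenerate: no variability across subjects
    tt <- list(statistic = c(t = if (mean(diffs) > 0) Inf else 0),
               p.value = if (mean(diffs) > 0) 0 else 1)
  } else {
    tt <- stats::t.test(real_means, null_means, paired = TRUE,
                        alternative = "greater")
  }
  list(
    t = unname(tt$statistic), p = tt$p.value,
    mean_diff = mean(real_means - null_means),
    boot_ci = unname(stats::quantile(boot_diff, c(0.025, 0.975))),
    subject_real = real_means, subject_null = null_means,
    procedure = paste(
      "subject means of real and null fidelity;",
      sprintf("%d-iteration bootstrap over subjects for the CI;", n_boot),
      "paired one-tailed t test (real > null) across subjects"
    )
  )
}

# O(n) sums for the Fisher-Lee circular correlation numerator/denominator.
fisher_lee_sums <- function(a_rad, b_rad) {
  A <- sum(cos(a_rad) * cos(b_rad)); B <- sum(sin(a_rad) * sin(b_rad))
  C <- sum(cos(a_rad) * sin(b_rad)); D <- sum(sin(a_rad) * cos(b_rad))
  list(num = A * B - C * D)
}

#' Fisher-Lee circular correlation with a permutation p value
#'
#' The T-linear circular association coefficient of Fisher and Lee (1983),
#' invariant to rotating either variable by a constant. Significance is
#' assessed by randomly permuting one variable (`n_perm` shuffles, two-sided
#' on |r|).
#'
#' @param angles_a,angles_b equal-length angle vectors in degrees
#'   (length >= 3).
#' @param n_perm number of permutations for the p value (default 10000).
#' @param seed RNG seed (optional).
#' @return list with `r`, `p`, `n`, `estimator`.
#' @examples
#' circular_correlation(c(10, 50, 200, 300), c(15, 60, 190, 310), n_perm = 99)
#' @export
circular_correlation <- function(angles_a, angles_b, n_perm = 10000,
                                 seed = NULL) {
  n <- length(angles_a)
  if (n < 3 || length(angles_b) != n) {
    stop("need two angle vectors of equal length >= 3")
  }
  a <- deg2rad(angles_a); b <- deg2rad(angles_b)
  denom_part <- function(x) {
    length(x)^2 - sum(cos(2 * x))^2 - sum(sin(2 * x))^2
  }
  denom <- sqrt(denom_part(a) * denom_part(b))
  if (denom < 1e-12) {
    stop("degenerate input: one angle set is (near) constant")
  }
  r_obs <- 4 * fisher_lee_sums(a, b)$num / denom
  p <- NA_real_
  if (n_perm > 0) {
    ca <- cos(a); sa <- sin(a)
    cb <- cos(b); sb <- sin(b)
    perm_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n)
        cbp <- cb[idx]; sbp <- sb[idx]
        4 * (sum(ca * cbp) * sum(sa * sbp) -
               sum(ca * sbp) * sum(sa * cbp)) / denom
      }, numeric(1))
    })
    p <- (1 + sum(abs(perm_stats) >= abs(r_obs))) / (n_perm + 1)
  }
  list(r = r_obs, p = p, n = n, estimator = "Fisher-Lee T-linear")
}

#' Compare pRF and encoding-model polar-angle preferences
#'
#' Restricts to voxels whose pRF centers lie at peripheral eccentricities
#' (at least `ecc_min`, matching the eccentricity range of the task
#' stimuli), derives each voxel's preferred polar angle from its channel
#' weights, and circularly correlates those with the pRF polar angles.
#'
#' @param prf_fits data.frame from [fit_prf()] (needs `angle_deg`,
#'   `ecc_deg`), rows indexed like the rows of `W`.
#' @param W voxels x channels weight matrix.
#' @param basis channel basis.
#' @param ecc_min eccentricity filter in degrees (default 5).
#' @param n_perm permutations for the correlation p value (default 10000).
#' @param seed RNG seed (optional).
#' @return list with `r`, `p`, `n`, `ecc_min`, and `voxels` (data.frame of
#'   voxel index, pRF angle, IEM peak angle for the retained voxels).
#' @export
compare_prf_iem_tuning <- function(prf_fits, W, basis, ecc_min = 5,
                                   n_perm = 10000, seed = NULL) {
  stopifnot(nrow(prf_fits) == nrow(W))
  keep <- which(prf_fits$ecc_deg >= ecc_min)
  if (length(keep) < 3) {
    stop("fewer than 3 voxels at eccentricity >= ", ecc_min)
  }
  peaks <- vapply(keep, function(v) {
    voxel_tuning_from_weights(W, basis, v)$peak_deg
  }, numeric(1))
  ok <- !is.na(peaks)
  if (sum(ok) < 3) stop("fewer than 3 voxels with defined tuning peaks")
  cc <- circular_correlation(prf_fits$angle_deg[keep][ok], peaks[ok],
                             n_perm = n_perm, seed = seed)
  list(r = cc$r, p = cc$p, n = cc$n, ecc_min = ecc_min,
       voxels = data.frame(voxel = keep[ok],
                           prf_angle_deg = prf_fits$angle_deg[keep][ok],
                           iem_peak_deg = peaks[ok]))
}

#' Delay-period activity relative to the pretrial baseline
#'
#' Per trial, averages each voxel's BOLD over the last `n_last` delay TRs and
#' subtracts the mean over a pretrial baseline window, then summarizes the
#' region mean split by whether the MGS target fell in each voxel's preferred
#' hemifield ("contra") or the opposite one ("ipsi"), with one-tailed t tests
#' against zero.
#'
#' @param bold voxel x TR matrix (runs concatenated in `run_id` order).
#' @param trials trial table.
#' @param voxel_hemifield character vector per voxel, `"left"` or `"right"`:
#'   the visual hemifield the voxel represents.
#' @param tr_s repetition time (default 1.5).
#' @param n_tr_per_run TRs per run (default inferred).
#' @param baseline_window seconds relative to stimulus onset for the
#'   baseline, default c(-4.5, 0) (the three pretrial TRs); trials without
#'   baseline coverage (e.g. the first of a run) are dropped.
#' @param n_last number of final delay TRs to average (default 4).
#' @return data.frame with one row per group (`contra`, `ipsi`):
#'   `mean_change`, `ci_lo`, `ci_hi` (95%), `t`, `p` (one-tailed > 0),
#'   `n_trials`.
#' @export
delay_activity_summary <- function(bold, trials, voxel_hemifield,
                                   tr_s = 1.5, n_tr_per_run = NULL,
                                   baseline_window = c(-4.5, 0),
                                   n_last = 4) {
  stopifnot(length(voxel_hemifield) == nrow(bold),
            all(voxel_hemifield %in% c("left", "right")))
  if (baseline_window[1] >= baseline_window[2]) {
    stop("baseline window must have positive length")
  }
  if (baseline_window[2] > min(trials$delay_onset_s - trials$stim_onset_s)) {
    stop("baseline window overlaps the delay period")
  }
  run_ids <- sort(unique(trials$run_id))
  if (is.null(n_tr_per_run)) n_tr_per_run <- ncol(bold) / length(run_ids)
  mid <- (seq_len(n_tr_per_run) - 0.5) * tr_s

  target_right <- cos(deg2rad(trials$mgs_angle_deg)) > 0
  is_right_vox <- voxel_hemifield == "right"
  rows <- list(contra = numeric(0), ipsi = numeric(0))
  for (k in seq_len(nrow(trials))) {
    offset <- (match(trials$run_id[k], run_ids) - 1) * n_tr_per_run
    in_delay <- which(mid >= trials$delay_onset_s[k] &
                        mid < trials$cue_onset_s[k])
    if (length(in_delay) < n_last) next
    dl <- utils::tail(in_delay, n_last) + offset
    b0 <- trials$stim_onset_s[k] + baseline_window
    in_base <- which(mid >= b0[1] & mid < b0[2]) + offset
    in_base <- in_base[in_base >= offset + 1]
    if (length(in_base) == 0) next
    change <- rowMeans(bold[, dl, drop = FALSE]) -
      rowMeans(bold[, in_base, drop = FALSE])
    match_vox <- is_right_vox == target_right[k]
    if (any(match_vox)) {
      rows$contra <- c(rows$contra, mean(change[match_vox]))
    }
    if (any(!match_vox)) {
      rows$ipsi <- c(rows$ipsi, mean(change[!match_vox]))
    }
  }
  summarize <- function(x, label) {
    if (stats::sd(x) < 1e-12) {
      # constant signal change: no evidence either way
      return(data.frame(group = label, mean_change = mean(x),
                        ci_lo = mean(x), ci_hi = mean(x), t = 0,
                        p = if (mean(x) > 0) 0 else 1,
                        n_trials = length(x)))
    }
    tt <- stats::t.test(x, alternative = "greater")
    ci <- stats::t.test(x)$conf.int
    data.frame(group = label, mean_change = mean(x), ci_lo = ci[1],
               ci_hi = ci[2], t = unname(tt$statistic), p = tt$p.value,
               n_trials = length(x))
  }
  rbind(summarize(rows$contra, "contra"), summarize(rows$ipsi, "ipsi"))
}
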