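#' Spatial inverted encoding model over polar angle
#'
#' Voxel responses are modeled as weighted sums of unimodal information
#' channels tiling polar angle. Channel weights are estimated by least
#' squares on training trials (the untransformed "same location" condition),
#' then inverted on held-out trials to recover channel coefficients, whose
#' basis-weighted sum is the reconstructed spatial sensitivity profile.
#'
#' @name iem
NULL

#' Construct the raised-cosine channel basis
#'
#' `n_channels` channels with centers equally spaced over [0, 360) and
#' profile `f_k(theta) = cos^2((theta - c_k)/2) = (1 + cos(theta - c_k))/2`,
#' the unimodal raised cosine with a single peak per cycle. The channels form
#' a partition up to a constant: `sum_k f_k(theta) = n_channels / 2` for all
#' theta.
#'
#' @param n_channels number of channels (>= 3; default 9, spacing 40
#'   degrees).
#' @return object of class `channel_basis`: list with `n_channels` and
#'   `centers_deg`.
#' @examples
#' b <- make_channel_basis()
#' rowSums(eval_channel_basis(b, 0:359))  # constant 4.5
#' @export
make_channel_basis <- function(n_channels = 9) {
  if (n_channels < 3) stop("n_channels must be >= 3")
  structure(
    list(n_channels = n_channels,
         centers_deg = (seq_len(n_channels) - 1) * 360 / n_channels),
    class = "channel_basis"
  )
}

#' Evaluate the channel basis at a set of angles
#'
#' @param basis a [make_channel_basis()] object.
#' @param theta_deg angles in degrees.
#' @return length(theta_deg) x n_channels matrix of channel responses.
#' @export
eval_channel_basis <- function(basis, theta_deg) {
  stopifnot(inherits(basis, "channel_basis"))
  delta <- outer(theta_deg, basis$centers_deg, `-`)
  (1 + cos(deg2rad(delta))) / 2
}

#' Average delay-period BOLD into one response per trial
#'
#' For each trial, averages each voxel's BOLD over the last `n_last` TRs
#' whose acquisition midpoints fall inside the memory-delay interval
#' (stimulus offset to saccade cue).
#'
#' @param bold voxel x TR matrix spanning all runs, runs concatenated in
#'   `run_id` order.
#' @param trials trial table with `run_id`, `delay_onset_s`, `cue_onset_s`.
#' @param tr_s repetition time in seconds (default 1.5).
#' @param n_tr_per_run TRs per run in `bold` (default inferred as
#'   `ncol(bold) / n_runs`).
#' @param n_last number of final delay TRs to average (default 4).
#' @return object of class `trial_responses`: list with `responses`
#'   (trials x voxels) and `trials`.
#' @export
delay_window_average <- function(bold, trials, tr_s = 1.5,
                                 n_tr_per_run = NULL, n_last = 4) {
  run_ids <- sort(unique(trials$run_id))
  if (is.null(n_tr_per_run)) n_tr_per_run <- ncol(bold) / length(run_ids)
  stopifnot(n_tr_per_run == round(n_tr_per_run))
  resp <- matrix(NA_real_, nrow(trials), nrow(bold))
  for (k in seq_len(nrow(trials))) {
    run_pos <- match(trials$run_id[k], run_ids)
    offset <- (run_pos - 1) * n_tr_per_run
    mid <- (seq_len(n_tr_per_run) - 0.5) * tr_s
    in_delay <- which(mid >= trials$delay_onset_s[k] &
                        mid < trials$cue_onset_s[k])
    if (length(in_delay) < n_last) {
      stop("delay period of trial ", k, " spans fewer than ", n_last, " TRs")
    }
    take <- utils::tail(in_delay, n_last) + offset
    resp[k, ] <- rowMeans(bold[, take, drop = FALSE])
  }
  structure(list(responses = resp, trials = trials),
            class = "trial_responses")
}

# Coerce a wm_dataset (either mode) into trial_responses.
as_trial_responses <- function(x, ...) {
  if (inherits(x, "trial_responses")) return(x)
  if (inherits(x, "wm_dataset")) {
    if (x$mode == "trialwise") {
      return(structure(list(responses = x$responses, trials = x$trials),
                       class = "trial_responses"))
    }
    return(delay_window_average(x$bold, x$trials, tr_s = x$tr_s,
                                n_tr_per_run = x$n_tr_per_run, ...))
  }
  stop("cannot interpret object as trial responses")
}

#' Combine trials pairwise within condition and angular bin
#'
#' Averages randomly chosen pairs of trials that share a transformation
#' condition and angular bin ("twofold mean"), halving the trial count while
#' preserving the counterbalancing of conditions over locations. Trial
#' angle labels become the circular mean of the paired trials' labels.
#'
#' @param trial_resp a `trial_responses` object ([delay_window_average()] or
#'   a trialwise dataset via the internal coercion).
#' @param seed RNG seed governing the pairing (optional).
#' @param allow_odd with the default FALSE, an odd trial count in any
#'   condition x bin cell is an error; TRUE instead carries one unpaired
#'   trial per odd cell through unaveraged (sessions with an odd number of
#'   run pairs have 5 trials per cell, which cannot be fully paired).
#' @return a `trial_responses` object with (about) half as many rows.
#' @export
twofold_combine <- function(trial_resp, seed = NULL, allow_odd = FALSE) {
  trial_resp <- as_trial_responses(trial_resp)
  trials <- trial_resp$trials
  cell <- interaction(trials$condition, trials$bin_index, drop = TRUE)
  counts <- table(cell)
  odd <- names(counts)[counts %% 2 != 0]
  if (length(odd) > 0 && !allow_odd) {
    stop("odd trial count in condition x bin cell(s): ",
         paste(odd, collapse = ", "))
  }
  with_seed(seed, {
    pair_rows <- list()
    for (cl in levels(cell)) {
      idx <- which(cell == cl)
      idx <- idx[sample(length(idx))]
      if (length(idx) %% 2 == 1) {
        # duplicate the leftover so the pair average returns it unchanged
        pair_rows[[cl]] <- rbind(
          matrix(idx[-length(idx)], ncol = 2, byrow = TRUE),
          c(idx[length(idx)], idx[length(idx)])
        )
      } else {
        pair_rows[[cl]] <- matrix(idx, ncol = 2, byrow = TRUE)
      }
    }
    pairs <- do.call(rbind, pair_rows)
    resp <- (trial_resp$responses[pairs[, 1], , drop = FALSE] +
               trial_resp$responses[pairs[, 2], , drop = FALSE]) / 2
    comb <- data.frame(
      condition = trials$condition[pairs[, 1]],
      bin_index = trials$bin_index[pairs[, 1]],
      bin_angle_deg = trials$bin_angle_deg[pairs[, 1]]
    )
    for (col in c("visual_angle_deg", "vgs_angle_deg", "mgs_angle_deg")) {
      comb[[col]] <- mapply(function(i, j) {
        circ_mean_deg(c(trials[[col]][i], trials[[col]][j]))
      }, pairs[, 1], pairs[, 2])
    }
    ord <- order(pairs[, 1])
    structure(list(responses = resp[ord, , drop = FALSE],
                   trials = comb[ord, , drop = FALSE]),
              class = "trial_responses")
  })
}

#' Estimate voxel-channel weights by least squares
#'
#' Solves `B_train = C_train %*% t(W)` for the voxels x channels weight
#' matrix W. With the raised-cosine basis the channel design has intrinsic
#' rank 3 (the channels span a constant plus one Fourier harmonic), so the
#' minimum-norm least-squares solution via the Moore-Penrose pseudoinverse is
#' used; it is exact for any weight pattern drawn from the same raised-cosine
#' tuning family. Training angles must achieve the basis's intrinsic rank
#' (at least 3 distinct angles).
#'
#' @param B_train trials x voxels matrix of training responses.
#' @param C_train trials x channels matrix of hypothetical channel
#'   coefficients (basis evaluated at each training trial's angle).
#' @return voxels x channels weight matrix.
#' @export
estimate_weights <- function(B_train, C_train) {
  if (nrow(B_train) != nrow(C_train)) {
    stop("B_train and C_train must have the same number of trial rows")
  }
  r <- qr(C_train)$rank
  intrinsic <- min(3, ncol(C_train))
  if (r < intrinsic) {
    stop("rank-deficient channel design: rank ", r, " from ",
         nrow(C_train), " training trials with ",
         length(unique(round(C_train %*% seq_len(ncol(C_train)), 8))),
         " distinct coefficient rows; need at least 3 distinct training angles")
  }
  t(MASS::ginv(C_train) %*% B_train)
}

#' Invert the encoding model and reconstruct sensitivity profiles
#'
#' Estimated channel coefficients for held-out data are
#' `C_test = B_test %*% t(pinv(W))`; the reconstruction for each trial is the
#' channel-coefficient-weighted sum of basis functions, sampled on a regular
#' angular grid.
#'
#' @param B_test trials x voxels matrix of held-out responses.
#' @param W voxels x channels weight matrix from [estimate_weights()].
#' @param basis the [make_channel_basis()] object used for training.
#' @param theta_deg angular sampling grid (default 0:359).
#' @return object of class `reconstruction_set`: list with `theta_deg`,
#'   `profiles` (trials x grid), `coef` (trials x channels), `basis`.
#' @export
invert_and_reconstruct <- function(B_test, W, basis, theta_deg = 0:359) {
  if (ncol(B_test) != nrow(W)) {
    stop("columns of B_test must match rows of W")
  }
  if (all(W == 0)) stop("weight matrix is identically zero; cannot invert")
  coef <- B_test %*% t(MASS::ginv(W))
  profiles <- coef %*% t(eval_channel_basis(basis, theta_deg))
  structure(list(theta_deg = theta_deg, profiles = profiles, coef = coef,
                 basis = basis),
            class = "reconstruction_set")
}

# Peak of a sampled circular profile; ties broken by circular mean of the
# argmax set. Returns NA for a flat profile.
profile_peak <- function(theta_deg, values, tol = 1e-10) {
  rng <- max(values) - min(values)
  if (rng < tol) return(NA_real_)
  at_max <- which(values >= max(values) - tol * max(1, abs(max(values))))
  if (length(at_max) == 1) return(theta_deg[at_max])
  circ_mean_deg(theta_deg[at_max])
}

#' Align reconstructions to their reference locations and average
#'
#' Each trial's profile is circularly shifted so that its reference angle
#' maps to 0 degrees, then the shifted profiles are averaged pointwise. When
#' channel coefficients are available the shift is evaluated analytically
#' from the basis (no interpolation error); otherwise circular linear
#' interpolation is used.
#'
#' @param recons a `reconstruction_set` from [invert_and_reconstruct()].
#' @param reference_angles one reference angle (degrees) per trial.
#' @return object of class `reconstruction`: list with `theta_deg`, `values`
#'   (average aligned profile), `n_trials`, `peak_deg`.
#' @export
align_and_average <- function(recons, reference_angles) {
  stopifnot(inherits(recons, "reconstruction_set"))
  n <- nrow(recons$profiles)
  if (length(reference_angles) != n) {
    stop("need one reference angle per trial (", n, " trials, ",
         length(reference_angles), " angles)")
  }
  theta <- recons$theta_deg
  aligned <- matrix(0, n, length(theta))
  for (t in seq_len(n)) {
    if (!is.null(recons$coef)) {
      fb <- eval_channel_basis(recons$basis, theta + reference_angles[t])
      aligned[t, ] <- as.vector(fb %*% recons$coef[t, ])
    } else {
      shifted <- wrap_angle(theta + reference_angles[t])
      aligned[t, ] <- circular_interp(recons$theta_deg,
                                      recons$profiles[t, ], shifted)
    }
  }
  values <- colMeans(aligned)
  structure(list(theta_deg = theta, values = values, n_trials = n,
                 peak_deg = profile_peak(theta, values)),
            class = "reconstruction")
}

# Periodic linear interpolation of a profile sampled on theta_grid.
circular_interp <- function(theta_grid, values, at) {
  n <- length(theta_grid)
  step <- 360 / n
  pos <- wrap_angle(at) / step
  lo <- floor(pos)
  frac <- pos - lo
  i0 <- (as.integer(lo) %% n) + 1
  i1 <- (as.integer(lo + 1) %% n) + 1
  values[i0] * (1 - frac) + values[i1] * frac
}

#' Polar-angle tuning curve of one voxel from its channel weights
#'
#' Sums all channels weighted by the voxel's estimated regression
#' coefficients; the peak of the resulting curve is the voxel's preferred
#' polar angle under the encoding model.
#'
#' @param W voxels x channels weight matrix.
#' @param basis the channel basis.
#' @param voxel_index row of W to summarize.
#' @param theta_deg sampling grid (default 0:359).
#' @return list with `theta_deg`, `values`, and `peak_deg` (NA, flagged by
#'   `flat = TRUE`, when the curve carries no angular modulation).
#' @export
voxel_tuning_from_weights <- function(W, basis, voxel_index,
                                      theta_deg = 0:359) {
  vals <- as.vector(eval_channel_basis(basis, theta_deg) %*% W[voxel_index, ])
  pk <- profile_peak(theta_deg, vals)
  list(theta_deg = theta_deg, values = vals, peak_deg = pk, flat = is.na(pk))
}

#' Train, invert, and align the encoding model on one dataset
#'
#' Convenience wrapper running the full single-pass IEM analysis: trial
#' responses are (optionally) twofold-combined, the model is trained on the
#' untransformed condition, inverted on the transformed conditions, and the
#' resulting reconstructions aligned to the chosen reference location and
#' averaged.
#'
#' @param dataset a `wm_dataset` or `trial_responses` object.
#' @param reference alignment reference: `"mgs"`, `"visual"`, or `"vgs"`.
#' @param basis channel basis (default 9 channels).
#' @param combine apply [twofold_combine()] first (default TRUE).
#' @param train_condition condition label used for training (default
#'   `"same"`).
#' @param permute_training shuffle the training data before fitting, to
#'   build permutation nulls: `"none"` (default), `"voxels"` (permute voxel
#'   columns of the training responses, destroying the voxel-to-tuning
#'   correspondence while preserving the scale of the weights), or
#'   `"labels"` (permute the training-trial angle labels).
#' @param allow_odd passed to [twofold_combine()].
#' @param seed RNG seed for pairing (and label permutation, if any).
#' @param theta_deg reconstruction grid (default 0:359).
#' @return list with `W`, `basis`, `recons` (`reconstruction_set` of test
#'   trials), `aligned` (`reconstruction`), `train_trials`, `test_trials`.
#' @export
run_iem <- function(dataset, reference = c("mgs", "visual", "vgs"),
                    basis = make_channel_basis(), combine = TRUE,
                    train_condition = "same",
                    permute_training = c("none", "voxels", "labels"),
                    seed = NULL, theta_deg = 0:359, allow_odd = FALSE) {
  reference <- match.arg(reference)
  permute_training <- match.arg(permute_training)
  tr <- as_trial_responses(dataset)
  if (combine) tr <- twofold_combine(tr, seed = seed, allow_odd = allow_odd)
  is_train <- tr$trials$condition == train_condition
  if (!any(is_train)) stop("no training trials with condition '",
                           train_condition, "'")
  if (all(is_train)) stop("no held-out transformed trials to reconstruct")
  train_angles <- tr$trials$visual_angle_deg[is_train]
  B_train <- tr$responses[is_train, , drop = FALSE]
  if (permute_training != "none") {
    perm_seed <- if (is.null(seed)) NULL else seed + 1L
    if (permute_training == "labels") {
      train_angles <- with_seed(perm_seed, sample(train_angles))
    } else {
      B_train <- with_seed(perm_seed, B_train[, sample(ncol(B_train)),
                                              drop = FALSE])
    }
  }
  C_train <- eval_channel_basis(basis, train_angles)
  W <- estimate_weights(B_train, C_train)
  recons <- invert_and_reconstruct(tr$responses[!is_train, , drop = FALSE],
                                   W, basis, theta_deg)
  ref_angles <- tr$trials[[paste0(reference, "_angle_deg")]][!is_train]
  aligned <- align_and_average(recons, ref_angles)
  list(W = W, basis = basis, recons = recons, aligned = aligned,
       train_trials = tr$trials[is_train, , drop = FALSE],
       test_trials = tr$trials[!is_train, , drop = FALSE])
}

#' Bootstrap the reconstruction over trial re-pairings
#'
#' Repeats the twofold pairing, training, inversion, and alignment with a
#' different random arrangement of trials per iteration, returning the
#' iteration-level aligned profiles and fidelity values. This checks that
#' results do not hinge on one particular recombination of trials.
#'
#' @param dataset a `wm_dataset` or `trial_responses` object.
#' @param reference alignment reference (default `"mgs"`).
#' @param n_iter number of bootstrap iterations (>= 1; the study-scale
#'   default is 10000, smaller values are appropriate for quick checks).
#' @param seed base RNG seed; iteration i uses `seed + 2 * i`.
#' @param basis channel basis.
#' @param keep_profiles return the per-iteration aligned profiles
#'   (default FALSE).
#' @param ... passed to [run_iem()].
#' @return list with `fidelity` (data.frame: iteration, basic, modified,
#'   peak_deg) and optionally `profiles` (n_iter x grid matrix).
#' @export
bootstrap_reconstruction <- function(dataset, reference = "mgs",
                                     n_iter = 10000, seed = 1,
                                     basis = make_channel_basis(),
                                     keep_profiles = FALSE, ...) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  rows <- vector("list", n_iter)
  profiles <- if (keep_profiles) matrix(NA_real_, n_iter, 360) else NULL
  for (i in seq_len(n_iter)) {
    res <- run_iem(dataset, reference = reference, basis = basis,
                   seed = seed + 2L * i, ...)
    fb <- fidelity_basic(res$aligned, true_angle = 0)
    fm <- fidelity_modified(res$aligned, true_angle = 0)
    rows[[i]] <- data.frame(iteration = i, basic = fb, modified = fm,
                            peak_deg = res$aligned$peak_deg)
    if (keep_profiles) profiles[i, ] <- res$aligned$values
  }
  out <- list(fidelity = do.call(rbind, rows))
  if (keep_profiles) out$profiles <- profiles
  out
}
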