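#' Detrend and z-score voxel time series per run
#'
#' For each voxel and run, removes the least-squares linear trend and divides
#' by the SD of the residuals, yielding series with mean 0 and SD 1 per
#' voxel-run. Voxels with (near-)zero residual variance in a run are returned
#' as zeros for that run and flagged.
#'
#' @param bold voxel x TR matrix, runs concatenated.
#' @param n_tr_per_run TRs per run (default: all columns form one run);
#'   each run must have at least 3 TRs.
#' @return matrix of the same shape; attribute `flat_voxels` holds the
#'   indices of voxel-runs (voxel, run) that were zeroed.
#' @examples
#' x <- matrix(1:20, nrow = 2, byrow = TRUE)  # pure ramps -> zeroed
#' detrend_zscore(x)
#' @export
detrend_zscore <- function(bold, n_tr_per_run = ncol(bold)) {
  stopifnot(is.matrix(bold), n_tr_per_run >= 3,
            ncol(bold) %% n_tr_per_run == 0)
  n_runs <- ncol(bold) / n_tr_per_run
  out <- bold
  flat <- NULL
  tt <- seq_len(n_tr_per_run)
  X <- cbind(1, tt - mean(tt))
  hat <- X %*% solve(crossprod(X), t(X))
  for (r in seq_len(n_runs)) {
    cols <- (r - 1) * n_tr_per_run + tt
    seg <- bold[, cols, drop = FALSE]
    resid <- seg - seg %*% t(hat)
    sds <- sqrt(rowSums(resid^2) / (n_tr_per_run - 1))
    zero <- sds < 1e-10
    sds[zero] <- 1
    out[, cols] <- resid / sds
    out[zero, cols] <- 0
    if (any(zero)) {
      flat <- rbind(flat, cbind(voxel = which(zero), run = r))
    }
  }
  attr(out, "flat_voxels") <- flat
  out
}
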