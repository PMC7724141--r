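#' Difference-of-gamma hemodynamic response function
#'
#' Canonical two-gamma HRF parameterized by its two delay parameters: the time
#' to peak of the positive lobe and the time to trough of the undershoot. Each
#' lobe is a gamma density (rate 1) whose mode sits at the requested delay; the
#' undershoot is scaled to a fixed fraction of the main lobe and the whole
#' kernel is normalized to unit peak. Only the two delays are free, matching
#' the usual practice of fitting time-to-peak and time-to-undershoot while
#' holding the lobe shapes fixed.
#'
#' @param t_s time points in seconds (>= 0).
#' @param peak_s time to peak of the positive lobe, seconds (default 6).
#' @param undershoot_s time to trough of the undershoot, seconds (default 16).
#' @param undershoot_ratio amplitude of the undershoot relative to the peak
#'   (default 1/6).
#' @return numeric vector of HRF values at `t_s`, unit peak.
#' @examples
#' h <- hrf_double_gamma(seq(0, 30, 1.5))
#' which.max(h)  # peak at ~6 s
#' @export
hrf_double_gamma <- function(t_s, peak_s = 6, undershoot_s = 16,
                             undershoot_ratio = 1 / 6) {
  stopifnot(peak_s > 0, undershoot_s > 0, undershoot_ratio >= 0)
  # gamma density with rate 1 has mode (shape - 1)
  g1 <- stats::dgamma(t_s, shape = peak_s + 1, rate = 1)
  g2 <- stats::dgamma(t_s, shape = undershoot_s + 1, rate = 1)
  m1 <- stats::dgamma(peak_s, shape = peak_s + 1, rate = 1)
  m2 <- stats::dgamma(undershoot_s, shape = undershoot_s + 1, rate = 1)
  h <- g1 / m1 - undershoot_ratio * g2 / m2
  mx <- max(h)
  if (mx > 0) h <- h / mx
  h
}

#' Convolve a neural drive time course with an HRF sampled on the TR grid
#'
#' Causal discrete convolution truncated to the input length, so the output
#' has one value per TR of the input.
#'
#' @param drive numeric vector (one value per TR) or a matrix with one column
#'   per time course (TR x series).
#' @param hrf HRF kernel sampled at the same TR spacing.
#' @return convolved series, same shape as `drive`.
#' @export
convolve_hrf <- function(drive, hrf) {
  if (is.matrix(drive)) {
    return(apply(drive, 2, convolve_hrf, hrf = hrf))
  }
  n <- length(drive)
  out <- stats::convolve(drive, rev(hrf), type = "open")[seq_len(n)]
  out
}

# HRF kernel on the TR grid, long enough to cover both lobes.
hrf_kernel <- function(tr_s, peak_s = 6, undershoot_s = 16,
                       undershoot_ratio = 1 / 6, duration_s = 32) {
  t_s <- seq(0, duration_s, by = tr_s)
  hrf_double_gamma(t_s, peak_s, undershoot_s, undershoot_ratio)
}
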