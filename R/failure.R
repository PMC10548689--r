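## sd of residuals from a linear fit over an index window
detrendedSd <- function(t, v, idx) {
  if (length(idx) < 3) return(NA_real_)
  f <- stats::lm.fit(cbind(1, t[idx]), v[idx])
  stats::sd(f$residuals)
}

#' Detect failure modes of a calibrated curve
#'
#' Classifies a thrombin (or amidolytic activity) curve:
#' \itemize{
#'   \item \code{no_curve} is propagated from upstream refusals;
#'   \item \code{nonphysical} when any absolute value exceeds
#'     \code{cap_mult} times the calibrator activity, when the curve
#'     re-ascends after its peak by more than \code{second_peak_frac} of
#'     the peak above the running post-peak minimum (the spurious
#'     second-peak / erratic-tail artifact of deep substrate depletion),
#'     or when the noise-amplification ratio exceeds
#'     \code{noise_amp_threshold};
#'   \item \code{ok} otherwise.
#' }
#' The noise-amplification ratio — detrended standard deviation over the
#' final 10\% of the record divided by that over the first 10\% (the
#' pre-lag window, where the true curve is flat) — is always reported.
#' Correction factors grow with fluorescence, so a correction that is
#' well-behaved early can still multiply read noise several-fold late in
#' the record; this ratio quantifies that amplification. The ratio rule
#' only engages when the tail variability is material
#' (> \code{noise_floor_frac} of the peak), so noiseless curves are not
#' flagged on numerically tiny ratios.
#'
#' @param curve a [ThrombinCurve-class] or [ActivityCurve-class].
#' @param activity calibrator activity E_cal, nM (scale for the cap).
#' @param cap_mult cap multiplier (default 10).
#' @param second_peak_frac re-ascent fraction of peak (default 0.2).
#' @param noise_amp_threshold ratio threshold (default 5).
#' @param noise_floor_frac minimum tail sd, as a fraction of peak, for the
#'   ratio rule to engage (default 0.02).
#' @return A [FailureStatus-class] with \code{noise_amplification} filled.
#' @export
detectFailure <- function(curve, activity = 100, cap_mult = 10,
                          second_peak_frac = 0.2, noise_amp_threshold = 5,
                          noise_floor_frac = 0.02) {
  stopifnot(is(curve, "ThrombinCurve") || is(curve, "ActivityCurve"))
  v <- if (is(curve, "ThrombinCurve")) curve@free_thrombin
       else curve@amidolytic
  t <- curve@times
  up <- curve@status
  if (up@code == "no_curve")
    return(failureStatus("no_curve", up@detail))
  n <- length(v)
  head_idx <- seq_len(max(3, floor(0.1 * n)))
  tail_idx <- seq(n - max(3, floor(0.1 * n)) + 1, n)
  sd_head <- detrendedSd(t, v, head_idx)
  sd_tail <- detrendedSd(t, v, tail_idx)
  peak <- max(abs(v), na.rm = TRUE)
  ratio <- if (is.na(sd_head) || sd_head < 1e-12 * max(peak, 1))
    NA_real_ else sd_tail / sd_head

  if (any(!is.finite(v)))
    return(failureStatus("nonphysical", "non-finite values", ratio))
  if (peak > cap_mult * activity)
    return(failureStatus("nonphysical", sprintf(
      "values exceed %g x calibrator activity", cap_mult), ratio))
  i_pk <- which.max(v)
  if (i_pk < n) {
    post <- v[i_pk:n]
    run_min <- cummin(post)
    if (any(post - run_min > second_peak_frac * v[i_pk]))
      return(failureStatus("nonphysical",
                           "curve re-ascends after its peak", ratio))
  }
  if (is.finite(ratio) && !is.na(sd_tail) &&
      sd_tail > noise_floor_frac * peak && ratio > noise_amp_threshold)
    return(failureStatus("nonphysical", sprintf(
      "noise amplification ratio %.2f exceeds %g", ratio,
      noise_amp_threshold), ratio))
  failureStatus(up@code, up@detail, ratio)
}
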