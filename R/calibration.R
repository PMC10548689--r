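## polynomial helpers, ascending coefficients (intercept first)
polyEval <- function(coeffs, t) {
  out <- 0
  for (k in rev(seq_along(coeffs))) out <- out * t + coeffs[k]
  out
}
polyDerivCoeffs <- function(coeffs) {
  n <- length(coeffs)
  if (n < 2) return(0)
  coeffs[-1] * seq_len(n - 1)
}

#' Correction specification for CAT-style processing
#'
#' @param poly_order calibrator polynomial order, 3 or 4.
#' @param smoother a [SmootherSpec-class] for the sample derivative.
#' @param range_policy \code{"refuse"}: any sample fluorescence outside
#'   the calibrator's fitted range voids the whole well (commercial-style
#'   non-reporting); \code{"extrapolate"}: the fitted polynomial is
#'   extended and the correction factor capped at \code{max_gain}.
#' @param alpha2m \code{"off"}, \code{"fixed_k"} or \code{"auto_k"}.
#' @param max_gain cap on the correction factor relative to the initial
#'   linear factor (dimensionless, > 1).
#' @param alpha2m_k the capture rate for \code{"fixed_k"}, 1/min.
#' @return A list with class \code{"CorrectionSpec"}.
#' @export
correctionSpec <- function(poly_order = 3,
                           smoother = smootherSpec("savgol"),
                           range_policy = c("refuse", "extrapolate"),
                           alpha2m = c("auto_k", "fixed_k", "off"),
                           max_gain = 20, alpha2m_k = NA_real_) {
  range_policy <- match.arg(range_policy)
  alpha2m <- match.arg(alpha2m)
  stopifnot(poly_order %in% c(3, 4), max_gain > 1)
  structure(list(poly_order = poly_order, smoother = smoother,
                 range_policy = range_policy, alpha2m = alpha2m,
                 max_gain = max_gain, alpha2m_k = alpha2m_k),
            class = "CorrectionSpec")
}

#' Fit the thrombin-calibrator curve
#'
#' Least-squares polynomial fit (order 3 or 4) of the calibrator well's
#' fluorescence versus time, after subtracting the calibrator's first
#' reading as the shared instrument baseline. The initial linear slope
#' (the fitted derivative at t = 0) is the single coefficient used by
#' internal linear calibration; the full polynomial supports
#' fluorescence-matched CAT correction.
#'
#' @param calib_well a [TGWell-class] with role \code{"calibrator"}.
#' @param order polynomial order, 3 or 4.
#' @param activity assigned calibrator activity, nM; defaults to the
#'   well condition's \code{calibrator_activity}.
#' @param t_range fitted time window, min; defaults to the full record.
#' @return A [CalibModel-class]. If the fitted derivative is not positive
#'   everywhere inside the window the model is flagged non-monotone (it
#'   cannot be inverted there) with a warning.
#' @export
fitCalibrator <- function(calib_well, order = 3, activity = NULL,
                          t_range = NULL) {
  stopifnot(is(calib_well, "TGWell"))
  if (calib_well@role != "calibrator")
    stop(sprintf("well '%s' does not have the calibrator role",
                 calib_well@well_id))
  if (!order %in% c(3, 4)) stop("order must be 3 or 4")
  t <- calib_well@times
  y0 <- calib_well@rfu
  if (length(t) < order + 3)
    stop(sprintf("calibrator needs at least %d points", order + 3))
  baseline <- y0[1]
  y <- y0 - baseline
  if (is.null(t_range)) t_range <- range(t)
  keep <- t >= t_range[1] & t <= t_range[2]
  if (y[length(y)] <= y[1])
    stop("calibrator fluorescence is not increasing over the record")
  fit <- stats::lm(y[keep] ~ stats::poly(t[keep], order, raw = TRUE))
  coeffs <- as.numeric(stats::coef(fit))
  slope0 <- coeffs[2]
  if (!is.finite(slope0) || slope0 <= 0)
    stop("fitted initial slope is not positive; calibrator unusable")
  if (is.null(activity)) activity <- calib_well@condition@calibrator_activity
  dcoef <- polyDerivCoeffs(coeffs)
  tt <- seq(t_range[1], t_range[2], length.out = 200)
  mono <- all(polyEval(dcoef, tt) > 0)
  if (!mono)
    warning("fitted calibrator derivative is not positive everywhere; ",
            "model flagged non-monotone")
  new("CalibModel", coeffs = coeffs, order = order, slope0 = slope0,
      activity = activity, f_range = range(y[keep]), t_range = t_range,
      baseline = baseline, monotone = mono)
}

#' Internal linear calibration
#'
#' Converts a rate curve to thrombin-equivalent activity with a single
#' calibration coefficient — the assigned calibrator activity divided by
#' the calibrator's initial linear slope — applied regardless of
#' fluorescence level. No artifact correction is performed, so this path
#' never refuses a curve.
#'
#' @param rate a [RateCurve-class] (RFU/min).
#' @param calib a [CalibModel-class].
#' @return An [ActivityCurve-class], method \code{"linear"}.
#' @export
internalLinear <- function(rate, calib) {
  stopifnot(is(rate, "RateCurve"), is(calib, "CalibModel"))
  new("ActivityCurve", times = rate@times,
      amidolytic = calib@activity * rate@rate / calib@slope0,
      status = failureStatus("ok"),
      correction_factor = numeric(0), method = "linear")
}

## invert the fitted calibrator polynomial: find t* with p(t*) = f on the
## monotone branch; lo/hi bracket may extend beyond the fitted window
invertCalibPoly <- function(coeffs, f, lo, hi) {
  g <- function(t) polyEval(coeffs, t) - f
  if (g(lo) > 0 || g(hi) < 0) return(NA_real_)
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

#' CAT fluorescence-matched artifact correction
#'
#' For each sample timepoint, locates the calibrator time at which the
#' fitted calibrator fluorescence equals the sample fluorescence (both on
#' the shared baseline), takes the calibrator velocity there, and scales
#' the sample rate by assigned-activity / matched-velocity. Because sample
#' and calibrator at equal fluorescence sit at the same optical saturation
#' and substrate-consumption state, this cancels the inner filter effect
#' and substrate-depletion artifacts — as long as the sample fluorescence
#' stays inside the calibrator's fitted range.
#'
#' Outside that range, \code{range_policy = "refuse"} voids the whole well
#' (\code{no_curve}); \code{"extrapolate"} extends the polynomial along
#' its increasing branch and caps the correction factor at
#' \code{max_gain} times the initial linear factor, flagging the curve
#' \code{nonphysical} when the cap engages.
#'
#' @param sample_well a [TGWell-class].
#' @param calib a [CalibModel-class] fitted on the paired calibrator.
#' @param spec a \code{CorrectionSpec} from [correctionSpec()].
#' @return An [ActivityCurve-class] with the per-timepoint correction
#'   factor (nM per RFU/min) in \code{@correction_factor}.
#' @export
catCorrect <- function(sample_well, calib, spec = correctionSpec()) {
  stopifnot(is(sample_well, "TGWell"), is(calib, "CalibModel"),
            inherits(spec, "CorrectionSpec"))
  t <- sample_well@times
  y <- sample_well@rfu - calib@baseline
  rate <- differentiate(t, spec$smoother, values = y)@rate
  dcoef <- polyDerivCoeffs(calib@coeffs)
  t0 <- calib@t_range[1]; t1 <- calib@t_range[2]
  f_lo <- polyEval(calib@coeffs, t0)
  f_hi <- polyEval(calib@coeffs, t1)

  # below the calibrator's first reading there is no artifact state to
  # mis-correct (smaller load than any calibrator point): the entry slope
  # applies there, and only the ceiling crossing voids a refused well
  out_of_range <- y > f_hi + 1e-9
  if (spec$range_policy == "refuse" && any(out_of_range)) {
    bad <- range(t[out_of_range])
    return(new("ActivityCurve", times = t,
               amidolytic = rep(NA_real_, length(t)),
               status = failureStatus("no_curve", sprintf(
                 "sample fluorescence outside calibrator range at %.3g-%.3g min",
                 bad[1], bad[2])),
               correction_factor = rep(NA_real_, length(t)),
               method = sprintf("cat%d_refuse", calib@order)))
  }

  # upper extension limit of the increasing branch for extrapolation:
  # stop where the fitted derivative first turns non-positive
  t_ext <- 3 * t1
  dtt <- seq(t1, 3 * t1, length.out = 300)
  dv <- polyEval(dcoef, dtt)
  if (any(dv <= 0)) t_ext <- dtt[which(dv <= 0)[1]]

  factor_cap <- spec$max_gain * calib@activity / calib@slope0
  cf <- numeric(length(t))
  clamped <- logical(length(t))
  nonpos_v <- FALSE
  for (i in seq_along(t)) {
    f <- y[i]
    if (f < f_lo) {
      vstar <- polyEval(dcoef, t0)       # below the window: entry slope
    } else {
      tstar <- invertCalibPoly(calib@coeffs, f, t0,
                               if (f <= f_hi) t1 else t_ext)
      vstar <- if (is.na(tstar)) NA_real_ else polyEval(dcoef, tstar)
    }
    if (is.na(vstar)) {                  # no real inversion root
      cf[i] <- factor_cap; clamped[i] <- TRUE
    } else if (vstar <= 0) {
      nonpos_v <- nonpos_v || !out_of_range[i]
      cf[i] <- factor_cap; clamped[i] <- TRUE
    } else {
      cf[i] <- calib@activity / vstar
      if (cf[i] > factor_cap) { cf[i] <- factor_cap; clamped[i] <- TRUE }
    }
  }
  status <- if (nonpos_v)
    failureStatus("nonphysical", "calibrator velocity <= 0 inside range")
  else if (any(clamped))
    failureStatus("nonphysical", sprintf(
      "correction factor capped at %d of %d timepoints",
      sum(clamped), length(t)))
  else failureStatus("ok")
  new("ActivityCurve", times = t, amidolytic = cf * rate, status = status,
      correction_factor = cf,
      method = sprintf("cat%d_%s", calib@order, spec$smoother@kind))
}
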