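#' @importFrom signal sgolayfilt
NULL

## central differences on the native grid: interior points use the
## two-neighbour slope, ends are one-sided
centralDiff <- function(t, y) {
  n <- length(t)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

assertUniformGrid <- function(t, what) {
  h <- diff(t)
  if (max(h) - min(h) > 1e-6 * stats::median(h))
    stop(sprintf("%s requires a uniform time grid", what))
  stats::median(h)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing via [signal::sgolayfilt()];
#' record ends are handled by the filter's truncated-window polynomial
#' fits. Exact on polynomials up to the chosen order.
#'
#' @param y values on a uniform grid.
#' @param window odd window length, points.
#' @param polyorder polynomial order (< window).
#' @return smoothed values, same length.
#' @export
smoothSavgol <- function(y, window = 5, polyorder = 2) {
  if (polyorder >= window) stop("polyorder must be < window")
  if (window %% 2 != 1) stop("window must be odd")
  if (window > length(y)) stop("window exceeds series length")
  if (any(!is.finite(y))) stop("NaN/Inf in input series")
  signal::sgolayfilt(y, p = polyorder, n = window)
}

#' Friedman's SuperSmoother
#'
#' Variable-span local linear smoothing ([stats::supsmu()], the canonical
#' implementation): tweeter/midrange/woofer spans with pointwise
#' leave-one-out span selection and blending when \code{span} is NA;
#' a fixed span otherwise. Deterministic.
#'
#' With automatic span selection the no-smoothing alternative is kept as
#' a cross-validation candidate: when the smoother's residuals exceed the
#' series' local noise floor (the neighbour-interpolation error), the
#' smallest available span is already biting into signal rather than
#' noise, and the series is returned unsmoothed. On noisy data the
#' canonical variable-span behaviour is unchanged.
#'
#' @param t abscissa (time, min), strictly increasing.
#' @param y values.
#' @param span fixed span in (0, 1], or NA for automatic selection
#'   (requires >= 10 points).
#' @return smoothed values on the same grid.
#' @export
smoothSuperSmoother <- function(t, y, span = NA_real_) {
  if (length(unique(t)) < 2) stop("constant-time input")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(y))) stop("NaN/Inf in input series")
  if (is.na(span) && length(t) < 10)
    stop("automatic span needs at least 10 points")
  fit <- stats::supsmu(t, y, span = if (is.na(span)) "cv" else span,
                       bass = 0)
  # supsmu returns values at sorted unique x; map back to the input grid
  out <- stats::approx(fit$x, fit$y, xout = t, rule = 2)$y
  if (is.na(span)) {
    n <- length(y)
    i <- 2:(n - 1)
    interp <- y[i - 1] + (y[i + 1] - y[i - 1]) *
      (t[i] - t[i - 1]) / (t[i + 1] - t[i - 1])
    noise_floor <- mean((y[i] - interp)^2)
    if (mean((y - out)^2) > noise_floor) return(y)
  }
  out
}

applySmoother <- function(t, y, spec) {
  switch(spec@kind,
    none = y,
    savgol = {
      assertUniformGrid(t, "Savitzky-Golay")
      smoothSavgol(y, spec@window, spec@polyorder)
    },
    supersmoother = smoothSuperSmoother(t, y, spec@span))
}

#' Differentiate a fluorescence curve into a rate curve
#'
#' First derivative in RFU/min on the native time grid. With
#' \code{kind = "none"} this is the plain central difference (one-sided at
#' the ends); \code{"savgol"} uses the Savitzky-Golay smoothed derivative
#' (local polynomial, derivative filter); \code{"supersmoother"} smooths
#' the series first, then takes central differences.
#'
#' @param x a [TGWell-class], or a numeric vector of times.
#' @param spec a [SmootherSpec-class].
#' @param values values when \code{x} is a time vector.
#' @return A [RateCurve-class].
#' @examples
#' w <- makeCalibratorWell(opticsParams(noise_sd = 0), conditionMeta())
#' rc <- differentiate(w, smootherSpec("savgol"))
#' @export
differentiate <- function(x, spec = smootherSpec("none"), values = NULL) {
  if (is(x, "TGWell")) {
    t <- x@times; y <- x@rfu
  } else {
    t <- x; y <- values
  }
  if (is.null(y) || length(t) != length(y))
    stop("times and values must have equal length")
  if (length(t) < 3) stop("need at least 3 points to differentiate")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(y))) stop("NaN/Inf in input series")
  rate <- switch(spec@kind,
    none = centralDiff(t, y),
    savgol = {
      h <- assertUniformGrid(t, "Savitzky-Golay derivative")
      if (spec@window > length(y)) stop("fewer points than window")
      signal::sgolayfilt(y, p = spec@polyorder, n = spec@window, m = 1,
                         ts = h)
    },
    supersmoother = centralDiff(t, smoothSuperSmoother(t, y, spec@span)))
  new("RateCurve", times = t, rate = rate, smoother_used = spec)
}
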