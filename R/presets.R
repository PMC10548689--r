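#' Analysis method presets
#'
#' The four processing paths compared throughout the package:
#' \describe{
#'   \item{linear}{internal linear calibration — one coefficient
#'     (activity / initial calibrator slope), no artifact correction,
#'     never refuses.}
#'   \item{cat3sg}{CAT correction with an order-3 calibrator polynomial
#'     and a Savitzky-Golay smoothed derivative, extrapolating outside
#'     the calibrator range (Origin-style).}
#'   \item{cat4ss}{CAT correction with an order-4 polynomial and
#'     SuperSmoother-smoothed derivative, extrapolating (Shiny-app
#'     style).}
#'   \item{cat_strict}{CAT correction, order 3, refusing any well whose
#'     fluorescence leaves the calibrator range
#'     (commercial-software-style non-reporting).}
#' }
#' All presets finish with automatic alpha-2-macroglobulin subtraction.
#'
#' @param name preset name.
#' @return A list with elements \code{label}, \code{type}
#'   (\code{"internal"} or \code{"cat"}), \code{spec} (a
#'   \code{CorrectionSpec}), and \code{smoother}.
#' @export
methodPreset <- function(name = c("linear", "cat3sg", "cat4ss",
                                  "cat_strict")) {
  name <- match.arg(name)
  switch(name,
    linear = list(label = "linear", type = "internal",
                  smoother = smootherSpec("none"),
                  spec = correctionSpec(3, smootherSpec("none"),
                                        "extrapolate")),
    cat3sg = list(label = "cat3sg", type = "cat",
                  smoother = smootherSpec("savgol"),
                  spec = correctionSpec(3, smootherSpec("savgol"),
                                        "extrapolate")),
    cat4ss = list(label = "cat4ss", type = "cat",
                  smoother = smootherSpec("supersmoother"),
                  spec = correctionSpec(4, smootherSpec("supersmoother"),
                                        "extrapolate")),
    cat_strict = list(label = "cat_strict", type = "cat",
                      smoother = smootherSpec("savgol"),
                      spec = correctionSpec(3, smootherSpec("savgol"),
                                            "refuse")))
}

## average replicate calibrator wells into one (element-wise mean RFU)
poolCalibrators <- function(plate, cal_ids) {
  wells <- lapply(cal_ids, function(id) getWell(plate, id))
  w <- wells[[1]]
  if (length(wells) > 1)
    w@rfu <- rowMeans(vapply(wells, function(x) x@rfu,
                             numeric(length(w@rfu))))
  w
}

#' Run one analysis method on one sample well
#'
#' Full pipeline: calibrator fit (per the preset's polynomial order),
#' internal linear or CAT fluorescence-matched calibration,
#' alpha-2-macroglobulin subtraction, failure detection, parameter
#' extraction.
#'
#' @param sample_well a [TGWell-class].
#' @param calib_well the paired calibrator [TGWell-class].
#' @param method preset name, see [methodPreset()].
#' @param alpha2m_mode \code{"auto_k"}, \code{"fixed_k"} or \code{"off"}.
#' @param alpha2m_k capture rate for \code{"fixed_k"}, 1/min.
#' @return list with \code{calib} ([CalibModel-class]), \code{activity}
#'   ([ActivityCurve-class]), \code{thrombin} ([ThrombinCurve-class]),
#'   \code{status} ([FailureStatus-class]), \code{params}
#'   ([TGParams-class]).
#' @examples
#' plate <- generatePlate("ife_spike", seed = 3, fviii_levels = 1,
#'                        amc_spike = 0, optics = list(noise_sd = 0))
#' res <- analyzeWell(getWell(plate, "S_c01_r1"),
#'                    getWell(plate, "CAL_c01_r1"), "cat3sg")
#' res$params
#' @export
analyzeWell <- function(sample_well, calib_well, method = "cat3sg",
                        alpha2m_mode = "auto_k", alpha2m_k = NA_real_) {
  preset <- methodPreset(method)
  calib <- fitCalibrator(calib_well, order = preset$spec$poly_order)
  ac <- if (preset$type == "internal") {
    internalLinear(differentiate(sample_well, preset$smoother), calib)
  } else {
    catCorrect(sample_well, calib, preset$spec)
  }
  tc <- if (alpha2m_mode == "off") {
    new("ThrombinCurve", times = ac@times, free_thrombin = ac@amidolytic,
        k_a2m_used = 0, status = ac@status)
  } else {
    subtractAlpha2m(ac, alpha2m_mode, k = alpha2m_k)
  }
  st <- detectFailure(tc, activity = calib@activity)
  tc@status <- st
  list(calib = calib, activity = ac, thrombin = tc, status = st,
       params = extractParams(tc))
}

#' Analyze every sample well of a plate
#'
#' @param plate a [TGPlate-class].
#' @param methods character vector of preset names.
#' @param with_truth add ground-truth TPH/ETP and relative errors when
#'   the plate retains ground truth.
#' @return data.frame, one row per (sample well, method): parameters,
#'   status code, noise amplification, and (synthetic plates) relative
#'   errors against ground truth.
#' @export
analyzePlate <- function(plate, methods = c("linear", "cat3sg", "cat4ss",
                                            "cat_strict"),
                         with_truth = TRUE) {
  stopifnot(is(plate, "TGPlate"))
  cd <- colData(plate)
  sample_ids <- cd$well_id[cd$role == "sample"]
  rows <- list()
  for (wid in sample_ids) {
    sw <- getWell(plate, wid)
    cal <- poolCalibrators(plate, calibratorFor(plate, sw@condition_id))
    gt <- if (with_truth) groundTruth(plate, wid) else NULL
    tph_true <- if (!is.null(gt)) max(gt@free_thrombin) else NA_real_
    etp_true <- if (!is.null(gt))
      trapezoid(gt@times, gt@free_thrombin) else NA_real_
    for (m in methods) {
      res <- analyzeWell(sw, cal, m)
      p <- res$params
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = wid, condition_id = sw@condition_id,
        label = sw@condition@label, method = m,
        lag_time = p@lag_time, time_to_peak = p@time_to_peak,
        tph = p@tph, etp = p@etp, status = p@status@code,
        noise_amplification = p@status@noise_amplification,
        tph_true = tph_true, etp_true = etp_true,
        tph_rel_err = if (is.finite(tph_true) && tph_true > 0)
          abs(p@tph - tph_true) / tph_true else NA_real_,
        etp_rel_err = if (is.finite(etp_true) && etp_true > 0)
          abs(p@etp - etp_true) / etp_true else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
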