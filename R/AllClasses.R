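#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Kinetic parameters of the thrombin-generation forward model
#'
#' Phenomenological description of the thrombin pulse in clotting plasma:
#' a gamma-shaped prothrombinase drive feeds free thrombin, which is removed
#' by antithrombin (first order, modulated by the residual antithrombin
#' level and by heparin) and captured by alpha-2-macroglobulin (a2M) into a
#' complex that no longer clots but still cleaves the small fluorogenic
#' substrate.
#'
#' @slot gen_amplitude peak of the prothrombinase drive, nM thrombin/min.
#' @slot gen_tau pulse time constant, min.
#' @slot gen_shape pulse shape exponent (dimensionless).
#' @slot k_at antithrombin-mediated decay rate at normal antithrombin, 1/min.
#' @slot at_fraction residual antithrombin level, fraction of normal in [0,1].
#' @slot heparin_factor multiplier on \code{k_at} when heparin is present
#'   (>= 1; 1 means no heparin).
#' @slot k_a2m alpha-2-macroglobulin capture rate, 1/min.
#' @slot a2m_amidolytic_fraction fraction of the a2M-bound thrombin's
#'   small-substrate activity that is retained, in [0,1].
#' @slot tf_pM tissue-factor trigger dose, pM; scales the drive amplitude
#'   (log-linearly) and sets the onset delay (proportional to 1/TF).
#' @seealso [kineticParams()]
#' @export
setClass("KineticParams", representation(
  gen_amplitude = "numeric", gen_tau = "numeric", gen_shape = "numeric",
  k_at = "numeric", at_fraction = "numeric", heparin_factor = "numeric",
  k_a2m = "numeric", a2m_amidolytic_fraction = "numeric", tf_pM = "numeric"))

setValidity("KineticParams", function(object) {
  v <- c(gen_amplitude = object@gen_amplitude, gen_tau = object@gen_tau,
         gen_shape = object@gen_shape, k_at = object@k_at,
         at_fraction = object@at_fraction,
         heparin_factor = object@heparin_factor, k_a2m = object@k_a2m,
         a2m_amidolytic_fraction = object@a2m_amidolytic_fraction,
         tf_pM = object@tf_pM)
  if (any(!is.finite(v)))
    return(paste("non-finite kinetic parameter:",
                 paste(names(v)[!is.finite(v)], collapse = ", ")))
  if (any(v[c("gen_amplitude", "k_at", "k_a2m", "tf_pM")] < 0))
    return("rates and amplitudes must be >= 0")
  if (object@gen_tau <= 0) return("gen_tau must be > 0")
  if (object@at_fraction < 0 || object@at_fraction > 1)
    return("at_fraction must lie in [0,1]")
  if (object@a2m_amidolytic_fraction < 0 ||
      object@a2m_amidolytic_fraction > 1)
    return("a2m_amidolytic_fraction must lie in [0,1]")
  if (object@heparin_factor < 1) return("heparin_factor must be >= 1")
  TRUE
})

#' Optical parameters of the plate-reader signal model
#'
#' Maps the cumulative fluorophore-equivalent load x(t) (cleaved AMC plus
#' spiked free AMC plus AFC bleed-equivalents, all in uM) to relative
#' fluorescence units through a saturating inner-filter-effect (IFE)
#' transform \eqn{\Phi(x) = K (1 - e^{-x/K})}, which is linear with unit
#' slope at the origin and approaches the identity as \code{ife_K} grows.
#'
#' @slot gain RFU per uM cleaved fluorophore in the linear limit.
#' @slot ife_K IFE saturation constant, uM fluorophore-equivalent.
#' @slot dark_offset instrument dark signal, RFU.
#' @slot noise_sd additive Gaussian read noise, RFU.
#' @slot afc_bleed_coeff RFU per uM AFC-substrate equivalent seen in the
#'   AMC recording channel.
#' @seealso [opticsParams()]
#' @export
setClass("OpticsParams", representation(
  gain = "numeric", ife_K = "numeric", dark_offset = "numeric",
  noise_sd = "numeric", afc_bleed_coeff = "numeric"))

setValidity("OpticsParams", function(object) {
  if (!all(is.finite(c(object@gain, object@ife_K, object@dark_offset,
                       object@noise_sd, object@afc_bleed_coeff))))
    return("non-finite optics parameter")
  if (object@gain <= 0) return("gain must be > 0")
  if (object@ife_K <= 0) return("ife_K must be > 0")
  if (object@noise_sd < 0) return("noise_sd must be >= 0")
  if (object@afc_bleed_coeff < 0) return("afc_bleed_coeff must be >= 0")
  TRUE
})

#' Per-condition assay metadata
#'
#' Everything that distinguishes one well condition from another on a
#' simulated plate: plasma state, spiked fluorophore, substrate loads,
#' turnover kinetics of the fluorogenic substrate, the assigned calibrator
#' activity and the recording schedule.
#'
#' @slot fviii_level factor VIII level, IU/mL (0 = severe hemophilia A
#'   plasma, 1 = normalized).
#' @slot amc_spike spiked free AMC, uM (final in-plasma fluorophore
#'   equivalent).
#' @slot substrate_total ZGGR-AMC concentration S0, uM.
#' @slot afc_substrate ZGGR-AFC concentration, uM.
#' @slot kcat substrate turnover number, 1/min.
#' @slot Km Michaelis constant, uM.
#' @slot calibrator_activity assigned Ta2MG calibrator activity E_cal,
#'   nM thrombin-equivalent.
#' @slot sampling_interval recording cadence, s.
#' @slot duration record length, min.
#' @slot label free-text condition label.
#' @seealso [conditionMeta()]
#' @export
setClass("ConditionMeta", representation(
  fviii_level = "numeric", amc_spike = "numeric", substrate_total = "numeric",
  afc_substrate = "numeric", kcat = "numeric", Km = "numeric",
  calibrator_activity = "numeric", sampling_interval = "numeric",
  duration = "numeric", label = "character"))

setValidity("ConditionMeta", function(object) {
  if (object@substrate_total < 0) return("substrate_total must be >= 0")
  if (object@amc_spike < 0) return("amc_spike must be >= 0")
  if (object@afc_substrate < 0) return("afc_substrate must be >= 0")
  if (object@sampling_interval <= 0) return("sampling_interval must be > 0")
  if (object@duration <= 0) return("duration must be > 0")
  if (object@Km <= 0 && object@kcat > 0)
    return("Km must be > 0 when kcat > 0")
  TRUE
})

#' Ground-truth trajectories of a simulated well
#'
#' True (noise-free, optics-free) state of the forward model on the
#' recording grid: free thrombin, the thrombin-a2M complex, the total
#' amidolytic activity E = T + f*a2MT that cleaves the substrate, and the
#' substrate/product pair. Substrate and product are empty until the
#' fluorescence stage has been run.
#'
#' @slot times time grid, min.
#' @slot free_thrombin T(t), nM.
#' @slot a2m_thrombin a2MT(t), nM.
#' @slot amidolytic E(t), nM thrombin-equivalent.
#' @slot substrate S(t), uM (filled by the fluorescence stage).
#' @slot product P(t), uM (filled by the fluorescence stage).
#' @export
setClass("GroundTruth", representation(
  times = "numeric", free_thrombin = "numeric", a2m_thrombin = "numeric",
  amidolytic = "numeric", substrate = "numeric", product = "numeric"))

setValidity("GroundTruth", function(object) {
  n <- length(object@times)
  if (length(object@free_thrombin) != n || length(object@a2m_thrombin) != n ||
      length(object@amidolytic) != n)
    return("trajectory lengths must match the time grid")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(object@free_thrombin < -1e-9) || any(object@a2m_thrombin < -1e-9))
    return("thrombin trajectories must be non-negative")
  if (length(object@substrate) &&
      (length(object@substrate) != n || length(object@product) != n))
    return("substrate/product must be empty or match the grid")
  TRUE
})

#' A single well's fluorescence record
#'
#' @slot well_id unique well identifier.
#' @slot role one of \code{"sample"} or \code{"calibrator"}.
#' @slot condition_id identifier of the condition this well belongs to.
#' @slot condition the [ConditionMeta-class] of the well.
#' @slot times recording times, min, strictly increasing.
#' @slot rfu fluorescence, RFU, same length as \code{times}.
#' @export
setClass("TGWell", representation(
  well_id = "character", role = "character", condition_id = "character",
  condition = "ConditionMeta", times = "numeric", rfu = "numeric"))

setValidity("TGWell", function(object) {
  if (!object@role %in% c("sample", "calibrator"))
    return("role must be 'sample' or 'calibrator'")
  if (length(object@times) != length(object@rfu))
    return("times and rfu must have equal length")
  if (length(object@times) < 8)
    return("a well needs at least 8 timepoints")
  if (any(diff(object@times) <= 0))
    return(sprintf("well '%s': times must be strictly increasing",
                   object@well_id))
  TRUE
})

#' Plate of thrombin-generation fluorescence time series
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one assay \code{"rfu"} (timepoints in rows, wells in columns), the time
#' grid in \code{rowData(x)$time_min}, per-well role/condition metadata in
#' \code{colData}, and in \code{metadata}: the sample-condition to
#' calibrator-well pairing, the generating scenario and seed (if
#' synthetic), and retained ground truth per well for testing.
#'
#' @export
setClass("TGPlate", contains = "SummarizedExperiment")

setValidity("TGPlate", function(object) {
  if (!"rfu" %in% assayNames(object)) return("assay 'rfu' is required")
  if (is.null(rowData(object)$time_min))
    return("rowData must carry time_min")
  tm <- rowData(object)$time_min
  if (length(tm) < 8) return("a plate needs at least 8 timepoints")
  if (any(diff(tm) <= 0)) return("time_min must be strictly increasing")
  cd <- colData(object)
  need <- c("well_id", "role", "condition_id")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must carry", paste(need, collapse = ", ")))
  if (anyDuplicated(cd$well_id))
    return(sprintf("duplicated well_id: %s",
                   paste(unique(cd$well_id[duplicated(cd$well_id)]),
                         collapse = ", ")))
  if (!all(cd$role %in% c("sample", "calibrator")))
    return("role must be 'sample' or 'calibrator'")
  pairing <- metadata(object)$pairing
  sc <- unique(cd$condition_id[cd$role == "sample"])
  bad <- sc[!vapply(sc, function(ci) {
    cal <- pairing[[ci]]
    length(cal) >= 1 && all(cal %in% cd$well_id) &&
      all(cd$role[match(cal, cd$well_id)] == "calibrator")
  }, logical(1))]
  if (length(bad))
    return(sprintf("sample condition(s) without a paired calibrator: %s",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' Fitted calibrator model
#'
#' Polynomial fit of the calibrator well's fluorescence-versus-time curve,
#' used for fluorescence-matched CAT correction, together with the initial
#' linear slope used for internal linear calibration.
#'
#' @slot coeffs polynomial coefficients of fitted F_cal(t), ascending
#'   powers (intercept first), RFU vs min.
#' @slot order polynomial order, 3 or 4.
#' @slot slope0 initial linear slope dF_cal/dt at t = 0, RFU/min.
#' @slot activity assigned calibrator activity E_cal, nM.
#' @slot f_range observed calibrator fluorescence range
#'   (baseline-adjusted), RFU.
#' @slot t_range fitted time window, min.
#' @slot baseline baseline fluorescence subtracted before fitting, RFU.
#' @slot monotone TRUE if the fitted derivative stays positive inside
#'   t_range (fit usable for inversion everywhere).
#' @export
setClass("CalibModel", representation(
  coeffs = "numeric", order = "numeric", slope0 = "numeric",
  activity = "numeric", f_range = "numeric", t_range = "numeric",
  baseline = "numeric", monotone = "logical"))

setValidity("CalibModel", function(object) {
  if (!object@order %in% c(3, 4)) return("order must be 3 or 4")
  if (length(object@coeffs) != object@order + 1)
    return("coeffs length must equal order + 1")
  if (object@slope0 <= 0) return("slope0 must be > 0")
  if (object@activity <= 0) return("activity must be > 0")
  if (diff(object@f_range) <= 0) return("f_range must have F_max > F_min")
  TRUE
})

#' Failure status of a processed curve
#'
#' @slot code one of \code{ok}, \code{out_of_range}, \code{nonphysical},
#'   \code{no_curve}.
#' @slot detail human-readable explanation.
#' @slot noise_amplification ratio of detrended tail standard deviation to
#'   detrended pre-lag standard deviation (dimensionless).
#' @export
setClass("FailureStatus", representation(
  code = "character", detail = "character", noise_amplification = "numeric"))

setValidity("FailureStatus", function(object) {
  if (!object@code %in% c("ok", "out_of_range", "nonphysical", "no_curve"))
    return("unknown failure code")
  TRUE
})

#' Calibrated amidolytic activity curve
#'
#' Thrombin-equivalent substrate-cleaving activity over time, before
#' alpha-2-macroglobulin subtraction. Produced by [internalLinear()] or
#' [catCorrect()].
#'
#' @slot times min.
#' @slot amidolytic nM thrombin-equivalent.
#' @slot status a [FailureStatus-class].
#' @slot correction_factor per-timepoint correction factor
#'   activity / v*(F), nM per RFU/min (diagnostics; empty for the internal
#'   linear path, whose factor is the constant activity/slope0).
#' @slot method label of the producing method.
#' @export
setClass("ActivityCurve", representation(
  times = "numeric", amidolytic = "numeric", status = "FailureStatus",
  correction_factor = "numeric", method = "character"))

setValidity("ActivityCurve", function(object) {
  if (length(object@times) != length(object@amidolytic))
    return("times and amidolytic must have equal length")
  if (object@status@code == "ok" && any(!is.finite(object@amidolytic)))
    return("amidolytic must be finite where status is ok")
  TRUE
})

#' Free-thrombin curve after alpha-2-macroglobulin subtraction
#'
#' @slot times min.
#' @slot free_thrombin nM; raw (unclipped) values, negatives retained.
#' @slot k_a2m_used the a2M capture rate used for the deconvolution, 1/min
#'   (amidolytic fraction folded in).
#' @slot status a [FailureStatus-class].
#' @export
setClass("ThrombinCurve", representation(
  times = "numeric", free_thrombin = "numeric", k_a2m_used = "numeric",
  status = "FailureStatus"))

setValidity("ThrombinCurve", function(object) {
  if (length(object@times) != length(object@free_thrombin))
    return("times and free_thrombin must have equal length")
  TRUE
})

#' Thrombin-generation curve parameters
#'
#' @slot lag_time min (NA when undefined).
#' @slot time_to_peak min.
#' @slot tph thrombin peak height, nM.
#' @slot etp endogenous thrombin potential (area under the curve), nM*min.
#' @slot status a [FailureStatus-class], propagated from the curve.
#' @export
setClass("TGParams", representation(
  lag_time = "numeric", time_to_peak = "numeric", tph = "numeric",
  etp = "numeric", status = "FailureStatus"))

setValidity("TGParams", function(object) {
  if (object@status@code == "ok") {
    if (is.finite(object@lag_time) && is.finite(object@time_to_peak) &&
        object@lag_time > object@time_to_peak + 1e-9)
      return("lag_time must not exceed time_to_peak")
    if (object@tph < 0 || object@etp < 0)
      return("tph and etp must be >= 0")
  }
  TRUE
})

#' Smoother specification for rate-curve extraction
#'
#' @slot kind \code{"savgol"}, \code{"supersmoother"}, or \code{"none"}
#'   (plain finite differences).
#' @slot window Savitzky-Golay window length in points (odd).
#' @slot polyorder Savitzky-Golay polynomial order.
#' @slot span SuperSmoother span in (0, 1], or \code{NA} for the
#'   cross-validated automatic span.
#' @export
setClass("SmootherSpec", representation(
  kind = "character", window = "numeric", polyorder = "numeric",
  span = "numeric"))

setValidity("SmootherSpec", function(object) {
  if (!object@kind %in% c("savgol", "supersmoother", "none"))
    return("kind must be savgol, supersmoother or none")
  if (object@kind == "savgol") {
    if (object@window %% 2 != 1) return("savgol window must be odd")
    if (object@window < object@polyorder + 2)
      return("savgol window must be >= polyorder + 2")
  }
  if (!is.na(object@span) && (object@span <= 0 || object@span > 1))
    return("span must lie in (0, 1] or be NA for auto")
  TRUE
})

#' Uncalibrated rate curve
#'
#' First derivative of a fluorescence record, RFU/min, on the native time
#' grid of the source well.
#'
#' @slot times min.
#' @slot rate RFU/min.
#' @slot smoother_used the [SmootherSpec-class] that produced it.
#' @export
setClass("RateCurve", representation(
  times = "numeric", rate = "numeric", smoother_used = "SmootherSpec"))

setValidity("RateCurve", function(object) {
  if (length(object@times) != length(object@rate))
    return("times and rate must have equal length")
  TRUE
})
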