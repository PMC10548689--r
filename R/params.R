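#' Construct kinetic parameters
#'
#' Defaults describe a normalized (FVIII-supplemented) plasma triggered at
#' 5 pM tissue factor: a gamma-shaped prothrombinase drive peaking at
#' 150 nM/min around 6 min, antithrombin decay of 0.9/min at normal
#' antithrombin, and slow alpha-2-macroglobulin capture (0.015/min) whose
#' complex retains full small-substrate activity — the source of the
#' sloped late-time fluorescence tail.
#'
#' @param gen_amplitude peak prothrombinase drive, nM thrombin/min.
#' @param gen_tau pulse time constant, min.
#' @param gen_shape pulse shape exponent.
#' @param k_at antithrombin decay rate at normal antithrombin, 1/min.
#' @param at_fraction residual antithrombin, fraction of normal in [0,1].
#' @param heparin_factor multiplier on \code{k_at} (>= 1).
#' @param k_a2m alpha-2-macroglobulin capture rate, 1/min.
#' @param a2m_amidolytic_fraction retained amidolytic activity of the
#'   a2M-thrombin complex, in [0,1].
#' @param tf_pM tissue-factor dose, pM.
#' @return A [KineticParams-class] object.
#' @examples
#' kp <- kineticParams(at_fraction = 0.05)  # antithrombin-deficient plasma
#' @export
kineticParams <- function(gen_amplitude = 150, gen_tau = 2, gen_shape = 3,
                          k_at = 0.9, at_fraction = 1, heparin_factor = 1,
                          k_a2m = 0.015, a2m_amidolytic_fraction = 1,
                          tf_pM = 5) {
  new("KineticParams", gen_amplitude = gen_amplitude, gen_tau = gen_tau,
      gen_shape = gen_shape, k_at = k_at, at_fraction = at_fraction,
      heparin_factor = heparin_factor, k_a2m = k_a2m,
      a2m_amidolytic_fraction = a2m_amidolytic_fraction, tf_pM = tf_pM)
}

#' Construct optical parameters
#'
#' Defaults give roughly 30 RFU per uM cleaved AMC with an inner-filter
#' saturation constant of 250 uM, so a 200 uM AMC spike already sits well
#' into the concave part of the response.
#'
#' @param gain RFU per uM fluorophore in the linear limit.
#' @param ife_K IFE saturation constant, uM.
#' @param dark_offset dark signal, RFU.
#' @param noise_sd additive Gaussian noise, RFU (0 = noiseless).
#' @param afc_bleed_coeff RFU per uM AFC-substrate equivalent in the AMC
#'   channel.
#' @return An [OpticsParams-class] object.
#' @export
opticsParams <- function(gain = 30, ife_K = 250, dark_offset = 50,
                         noise_sd = 3, afc_bleed_coeff = 1.5) {
  new("OpticsParams", gain = gain, ife_K = ife_K, dark_offset = dark_offset,
      noise_sd = noise_sd, afc_bleed_coeff = afc_bleed_coeff)
}

#' Construct condition metadata
#'
#' Defaults follow the commercial CAT layout: 416 uM ZGGR-AMC, a 100 nM
#' thrombin-equivalent calibrator, 30 s sampling for 60 min. Substrate
#' turnover defaults (kcat 54/min, Km 120 uM) put the assay in the partly
#' consumed regime where calibrator-based correction matters.
#'
#' @param fviii_level IU/mL.
#' @param amc_spike spiked free AMC, uM (final in-plasma concentration).
#' @param substrate_total ZGGR-AMC S0, uM.
#' @param afc_substrate ZGGR-AFC, uM.
#' @param kcat substrate turnover, 1/min.
#' @param Km Michaelis constant, uM.
#' @param calibrator_activity assigned calibrator activity, nM.
#' @param sampling_interval s.
#' @param duration min.
#' @param label condition label; autogenerated if empty.
#' @return A [ConditionMeta-class] object.
#' @export
conditionMeta <- function(fviii_level = 1, amc_spike = 0,
                          substrate_total = 416, afc_substrate = 0,
                          kcat = 54, Km = 120, calibrator_activity = 100,
                          sampling_interval = 30, duration = 60,
                          label = "") {
  if (!nzchar(label))
    label <- sprintf("FVIII=%g_AMC=%g_S0=%g", fviii_level, amc_spike,
                     substrate_total)
  new("ConditionMeta", fviii_level = fviii_level, amc_spike = amc_spike,
      substrate_total = substrate_total, afc_substrate = afc_substrate,
      kcat = kcat, Km = Km, calibrator_activity = calibrator_activity,
      sampling_interval = sampling_interval, duration = duration,
      label = label)
}

#' Construct a smoother specification
#'
#' @param kind \code{"savgol"}, \code{"supersmoother"} or \code{"none"}.
#' @param window Savitzky-Golay window (odd number of points).
#' @param polyorder Savitzky-Golay polynomial order.
#' @param span SuperSmoother span, or NA for cross-validated automatic
#'   span selection.
#' @return A [SmootherSpec-class] object.
#' @export
smootherSpec <- function(kind = c("none", "savgol", "supersmoother"),
                         window = 5, polyorder = 2, span = NA_real_) {
  kind <- match.arg(kind)
  new("SmootherSpec", kind = kind, window = window, polyorder = polyorder,
      span = as.numeric(span))
}

#' Construct a failure status
#' @param code status code.
#' @param detail free-text detail.
#' @param noise_amplification tail/pre-lag detrended sd ratio.
#' @return A [FailureStatus-class] object.
#' @export
failureStatus <- function(code = "ok", detail = "",
                          noise_amplification = NA_real_) {
  new("FailureStatus", code = code, detail = detail,
      noise_amplification = noise_amplification)
}
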