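#' Saturating inner-filter-effect transform
#'
#' \eqn{\Phi(x) = K (1 - e^{-x/K})}: strictly increasing, concave,
#' \eqn{\Phi(x) \le x} with equality only at 0, unit slope at the origin,
#' and the identity in the limit \eqn{K \to \infty}.
#'
#' @param x fluorophore-equivalent load, uM (vectorized).
#' @param ife_K saturation constant, uM.
#' @return transformed load, uM-equivalent.
#' @export
ifePhi <- function(x, ife_K) {
  stopifnot(ife_K > 0)
  ife_K * (1 - exp(-x / ife_K))
}

## run expr with a private RNG stream, restoring the caller's state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## integrate substrate consumption for a given amidolytic activity E(t) [nM]
## over the shared ZGGR peptide pool (AMC + AFC substrates, same kcat/Km);
## returns substrate/product split per fluorophore
consumeSubstrate <- function(times, amidolytic_nM, condition) {
  s0_amc <- condition@substrate_total
  s0_afc <- condition@afc_substrate
  s0 <- s0_amc + s0_afc
  if (s0 <= 0 || condition@kcat <= 0) {
    z <- rep(0, length(times))
    return(list(S_amc = rep(s0_amc, length(times)), P_amc = z,
                S_afc = rep(s0_afc, length(times)), P_afc = z))
  }
  if (condition@Km <= 0) stop("Km must be > 0 when kcat > 0")
  Efun <- stats::approxfun(times, amidolytic_nM / 1000, rule = 2)  # -> uM
  rhs <- function(t, y, parms) {
    S <- max(y[1], 0)
    list(-condition@kcat * Efun(t) * S / (condition@Km + S))
  }
  sol <- deSolve::lsoda(c(S = s0), times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  S_tot <- pmin(pmax(sol[, "S"], 0), s0)
  # equal specificity: the pools are consumed in proportion
  S_amc <- S_tot * s0_amc / s0
  S_afc <- S_tot * s0_afc / s0
  list(S_amc = S_amc, P_amc = s0_amc - S_amc,
       S_afc = S_afc, P_afc = s0_afc - S_afc)
}

#' Simulate a fluorescence record from ground-truth activity
#'
#' Integrates Michaelis-Menten substrate consumption
#' \eqn{dS/dt = -k_{cat} E(t) S/(K_m + S)} driven by the ground-truth
#' amidolytic activity, forms the fluorophore-equivalent load
#' \eqn{x(t) = P_{AMC}(t) + \mathrm{spike} + (c_{bleed}/\mathrm{gain}) P_{AFC}(t)},
#' and reads it out as
#' \eqn{F(t) = \mathrm{dark} + \mathrm{gain}\,\Phi(x(t)) + c_{bleed} S^{AFC}_0 + \epsilon}
#' with seed-controlled additive Gaussian noise.
#'
#' @param truth a [GroundTruth-class] on the condition's grid.
#' @param optics an [OpticsParams-class].
#' @param condition a [ConditionMeta-class].
#' @param seed integer seed for the noise draw.
#' @param well_id well identifier.
#' @param role \code{"sample"} or \code{"calibrator"}.
#' @param condition_id condition identifier stored on the well.
#' @param early_drop_amp amplitude (RFU) of the optional early-minutes
#'   baseline-drop transient; 0 (default) disables it.
#' @param early_drop_tau transient time constant, min.
#' @param return_truth if TRUE, return \code{list(well, truth)} with the
#'   substrate/product trajectories filled into the ground truth.
#' @return A [TGWell-class] (or a list, see \code{return_truth}).
#' @export
simulateFluorescence <- function(truth, optics, condition, seed = 1L,
                                 well_id = "S01", role = "sample",
                                 condition_id = "c1",
                                 early_drop_amp = 0, early_drop_tau = 2,
                                 return_truth = FALSE) {
  validObject(truth); validObject(optics); validObject(condition)
  grid <- timeGrid(condition)
  if (length(grid) != length(truth@times) ||
      max(abs(grid - truth@times)) > 1e-9)
    stop("ground-truth grid does not match the condition grid")
  cons <- consumeSubstrate(truth@times, truth@amidolytic, condition)
  x <- cons$P_amc + condition@amc_spike +
    (optics@afc_bleed_coeff / optics@gain) * cons$P_afc
  f <- optics@dark_offset + optics@gain * ifePhi(x, optics@ife_K) +
    optics@afc_bleed_coeff * condition@afc_substrate
  if (early_drop_amp > 0)
    f <- f - early_drop_amp * exp(-truth@times / early_drop_tau)
  if (optics@noise_sd > 0)
    f <- f + withSeed(seed, stats::rnorm(length(f), 0, optics@noise_sd))
  well <- new("TGWell", well_id = well_id, role = role,
              condition_id = condition_id, condition = condition,
              times = truth@times, rfu = f)
  if (!return_truth) return(well)
  truth@substrate <- cons$S_amc + cons$S_afc
  truth@product <- (condition@substrate_total + condition@afc_substrate) -
    truth@substrate
  list(well = well, truth = truth)
}

#' Simulate a thrombin-calibrator well
#'
#' Calibrator wells carry the thrombin-a2M complex at a known, constant
#' substrate-cleaving activity and no thrombin generation; they go through
#' the identical substrate/optics pipeline as sample wells.
#'
#' @inheritParams simulateFluorescence
#' @param condition the condition; \code{calibrator_activity} must be > 0.
#'   Note the calibrator shares the condition's substrate and optics but
#'   carries no AMC spike (the spike is a property of the sample plasma).
#' @return A [TGWell-class] with role \code{"calibrator"} (or a list with
#'   the ground truth, see \code{return_truth}).
#' @export
makeCalibratorWell <- function(optics, condition, seed = 2L,
                               well_id = "CAL1", condition_id = "c1",
                               early_drop_amp = 0, early_drop_tau = 2,
                               return_truth = FALSE) {
  validObject(optics); validObject(condition)
  if (condition@calibrator_activity <= 0)
    stop("calibrator_activity must be > 0")
  times <- timeGrid(condition)
  e <- rep(condition@calibrator_activity, length(times))
  truth <- new("GroundTruth", times = times,
               free_thrombin = rep(0, length(times)),
               a2m_thrombin = e, amidolytic = e,
               substrate = numeric(0), product = numeric(0))
  cal_cond <- condition
  cal_cond@amc_spike <- 0
  simulateFluorescence(truth, optics, cal_cond, seed = seed,
                       well_id = well_id, role = "calibrator",
                       condition_id = condition_id,
                       early_drop_amp = early_drop_amp,
                       early_drop_tau = early_drop_tau,
                       return_truth = return_truth)
}
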