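#' @importFrom deSolve lsoda
NULL

## TF dose handling: the drive amplitude scales log-linearly with the
## trigger dose around the 5 pM reference, and the onset is delayed in
## proportion to 1/TF (low TF -> long initiation phase).
TF_REF_PM <- 5
TF_AMP_SLOPE <- 0.25
TF_DELAY_COEF <- 2        # min * pM

tfAmplitudeScale <- function(tf_pM) {
  if (tf_pM <= 0) return(0)
  max(0.02, 1 + TF_AMP_SLOPE * log(tf_pM / TF_REF_PM))
}

tfOnsetDelay <- function(tf_pM) {
  if (tf_pM <= 0) return(Inf)
  TF_DELAY_COEF / tf_pM - TF_DELAY_COEF / TF_REF_PM
}

## FVIII dependence of the drive: severe hemophilia A plasma retains a
## small residual drive (~8%); supplementation to 1 IU/mL restores it.
fviiiAmplitudeScale <- function(fviii_level) {
  0.08 + 0.92 * min(max(fviii_level, 0), 1)
}

#' Prothrombinase drive of the forward model
#'
#' Gamma-shaped pulse \eqn{g(t) = A \, (t'/\tau)^s e^{-t'/\tau} / (s^s e^{-s})}
#' with \eqn{t' = t - d(\mathrm{TF})}, normalized so its peak equals the
#' amplitude; the amplitude is scaled by the FVIII level and
#' (log-linearly) by the tissue-factor dose, and the onset delay grows as
#' 1/TF.
#'
#' @param t time, min (vectorized).
#' @param kinetics a [KineticParams-class].
#' @param condition a [ConditionMeta-class] (for the FVIII level).
#' @return drive, nM thrombin/min.
#' @export
thrombinDrive <- function(t, kinetics, condition) {
  amp <- kinetics@gen_amplitude * tfAmplitudeScale(kinetics@tf_pM) *
    fviiiAmplitudeScale(condition@fviii_level)
  if (amp <= 0) return(rep(0, length(t)))
  tp <- t - tfOnsetDelay(kinetics@tf_pM)
  s <- kinetics@gen_shape
  tau <- kinetics@gen_tau
  norm <- if (s > 0) s^s * exp(-s) else 1
  g <- ifelse(tp > 0, amp * (tp / tau)^s * exp(-tp / tau) / norm, 0)
  g[!is.finite(g)] <- 0
  g
}

timeGrid <- function(condition) {
  dt <- condition@sampling_interval / 60   # s -> min
  seq(0, condition@duration, by = dt)
}

#' Simulate the free-thrombin and a2M-thrombin trajectories
#'
#' Solves the two-compartment inhibition model
#' \deqn{dT/dt = g(t) - (k_{AT} \cdot at \cdot hep + k_{a2M}) T, \qquad
#'       d\alpha_2MT/dt = k_{a2M} T}
#' on the condition's recording grid and returns the ground truth with the
#' amidolytic activity \eqn{E = T + f \cdot \alpha_2MT}. Substrate and
#' product are left empty; [simulateFluorescence()] fills them.
#'
#' @param kinetics a [KineticParams-class].
#' @param condition a [ConditionMeta-class].
#' @param drive optional drive function \code{function(t) -> nM/min}
#'   overriding [thrombinDrive()] (used by tests with analytic drives).
#' @return A [GroundTruth-class] (thrombin components only).
#' @examples
#' gt <- simulateFreeThrombin(kineticParams(), conditionMeta())
#' max(gt@free_thrombin)    # thrombin peak, nM
#' @export
simulateFreeThrombin <- function(kinetics, condition, drive = NULL) {
  validObject(kinetics); validObject(condition)
  times <- timeGrid(condition)
  if (length(times) < 2 || any(times < 0)) stop("invalid time grid")
  k_decay <- kinetics@k_at * kinetics@at_fraction * kinetics@heparin_factor
  k_a2m <- kinetics@k_a2m
  g <- if (is.null(drive)) function(t) thrombinDrive(t, kinetics, condition)
       else drive
  rhs <- function(t, y, parms) {
    list(c(g(t) - (k_decay + k_a2m) * y[1], k_a2m * y[1]))
  }
  sol <- deSolve::lsoda(c(T = 0, A = 0), times, rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-9)
  Tt <- pmax(sol[, "T"], 0)
  At <- pmax(sol[, "A"], 0)
  new("GroundTruth", times = times, free_thrombin = Tt, a2m_thrombin = At,
      amidolytic = Tt + kinetics@a2m_amidolytic_fraction * At,
      substrate = numeric(0), product = numeric(0))
}
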