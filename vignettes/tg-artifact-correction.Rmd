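---
title: "Modelling and correcting optical artifacts in fluorogenic thrombin generation assays"
author: "tgedge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and correcting optical artifacts in fluorogenic thrombin generation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgedge)
```

## The problem

The fluorogenic thrombin generation (TG) assay follows clotting plasma
through a slow fluorogenic substrate (ZGGR-AMC): thrombin cleaves the
substrate, the released AMC fluoresces, and the first derivative of the
fluorescence record is — ideally — proportional to the active thrombin
concentration. Three physical effects bend that proportionality:

* the **inner filter effect (IFE)**: at high fluorophore concentration the
  emitted light is re-absorbed, so fluorescence is a concave, saturating
  function of the cumulative fluorophore load;
* **substrate depletion**: the Michaelis–Menten cleavage rate falls as
  substrate is consumed;
* the **thrombin–α~2~-macroglobulin complex (Tα~2~MG)**: thrombin captured
  by α~2~M no longer clots but still cleaves the small substrate, leaving a
  sloped fluorescence tail after free thrombin is gone.

The calibrated automated thrombogram (CAT) method addresses the first two
by running a parallel *calibrator* well — plasma plus Tα~2~MG at a known,
constant substrate-cleaving activity — and comparing sample and calibrator
at **matched fluorescence levels**. This package simulates plates where
each artifact can be forced to arbitrary severity, runs the correction
algorithms on them, and finds the severity at which each algorithm stops
producing acceptable curves (its *edge of failure*).

## The forward model

### Kinetics

Free thrombin $T$ and the complex $\alpha_2MT$ follow

$$\frac{dT}{dt} = g(t) - (k_{AT}\,a\,h + k_{\alpha_2M})\,T,
\qquad \frac{d\,\alpha_2MT}{dt} = k_{\alpha_2M}\,T,$$

with a gamma-shaped prothrombinase drive
$g(t) \propto (t'/\tau)^s e^{-t'/\tau}$ normalised so its maximum equals
`gen_amplitude`. Here $a$ is the residual antithrombin fraction
(`at_fraction`; 1 = normal plasma, 0.05 = antithrombin-depleted plasma
reconstituted with 5% normal plasma) and $h \ge 1$ a heparin multiplier.
The tissue-factor dose scales the amplitude log-linearly around the 5 pM
reference and delays the onset in proportion to $1/\mathrm{TF}$ — a
phenomenological mapping that reproduces the qualitative dose dependence of
lag time and peak without a factor-by-factor cascade model (an explicit
non-goal). The measured amidolytic activity is
$E = T + f\,\alpha_2MT$ with $f$ the retained small-substrate activity of
the complex (default 1: the complex is conventionally taken to cleave
small substrates at an essentially unchanged rate — it is, after all, what
the calibrator is made of).

The ODEs are solved with `deSolve::lsoda` at tolerances (1e-9) far below
any downstream effect.

### Optics

Substrate consumption follows
$dS/dt = -k_{cat} E(t)\, S/(K_m + S)$; AMC- and AFC-based substrates share
one peptide pool (equal specificity) and are consumed in proportion. The
fluorophore-equivalent load is

$$x(t) = P_{AMC}(t) + \mathrm{spike} + \frac{c_{bleed}}{\mathrm{gain}}\,P_{AFC}(t),$$

and the recorded signal

$$F(t) = \mathrm{dark} + \mathrm{gain}\,\Phi(x(t)) + c_{bleed}\,S^{AFC}_0
+ \varepsilon, \qquad
\Phi(x) = K\left(1 - e^{-x/K}\right).$$

$\Phi$ is the IFE transform: strictly increasing, concave,
$\Phi(x)\le x$, unit slope at the origin, and the identity as
$K \to \infty$. The literature gives no closed form for the IFE; this
single-parameter exponential saturation was chosen for exactly those four
properties. Uncleaved AFC substrate contributes a constant baseline in the
AMC channel (`afc_bleed_coeff` per µM), cleaved AFC product bleeds through
inside the load. Noise is additive Gaussian, seed-controlled; shot noise
was considered and deferred — additive noise already reproduces the
noise-amplification phenomenon of interest. An optional early-minutes
exponential baseline transient (off by default) emulates the
plasma-settling drop sometimes seen in the first ~5 min, which is an
optical disturbance unrelated to the IFE.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `gen_amplitude` | 150 nM/min | gives TPH ≈ 156 nM, ETP ≈ 1460 nM·min, ttp ≈ 7 min at 5 pM TF — a realistic normal-plasma thrombogram |
| `gen_tau`, `gen_shape` | 2 min, 3 | lag ≈ 3 min and a ~5-min-wide peak |
| `k_at` | 0.9 /min | sub-minute thrombin half-life in normal plasma |
| `k_a2m` | 0.015 /min | terminal Tα~2~MG level ≈ 22 nM, a visible but not dominant tail |
| `fviii_level` scaling | 0.08 + 0.92·FVIII | severe hemophilia A retains a small residual drive (TPH ≈ 12 nM) |
| `kcat`, `Km` | 54 /min, 120 µM | ZGGR-AMC is deliberately slow; these values let the 100 nM calibrator consume ≈ 55% of 416 µM substrate in 60 min, and place the refusal edge inside the studied spike range |
| `calibrator_activity` | 100 nM | vendor-assigned activities are of this order; configurable because the true assigned value is proprietary |
| `substrate_total` | 416 µM | commercial CAT load (800 µM for the in-house style assays) |
| `gain`, `ife_K` | 30 RFU/µM, 250 µM | a 200 µM spike sits deep in the concave region, as in the forced-IFE experiments |
| `sampling_interval`, `duration` | 30 s, 60 min | within the 24–52 s cadences and 40–60 min records used on real readers |

Spiked AMC (`amc_spike`) is interpreted as the **final in-plasma
fluorophore-equivalent concentration**; the source protocols are ambiguous
between stock and final concentrations, and the final concentration is the
quantity the optics actually see. A paired calibrator shares its
condition's substrate and optics state but **not** the AMC spike — the
spike is a property of the sample plasma, and this is what makes the
commercial-style refusal reachable: a spiked sample can start above the
fluorescence ceiling the calibrator ever reaches.

## The analysis stack

### Rate curves

`differentiate()` converts RFU to RFU/min on the native time grid:
central differences (one-sided ends) for `kind = "none"`, the
Savitzky–Golay derivative filter (`signal::sgolayfilt`, default window 5 /
order 2 — the smallest legal smoothed-derivative stencil; the plain first
difference is available as `kind = "none"`), or Friedman's SuperSmoother
(`stats::supsmu`, spans 0.05/0.2/0.5, automatic span by cross-validation)
followed by central differences. All outputs stay on the native grid so
rate curves, calibrator fits and ETP integrals share one convention.

One refinement to the automatic-span policy: the unsmoothed series is kept
as a cross-validation candidate. When the smoother's residuals exceed the
series' neighbour-interpolation noise floor, the smallest available span is
already flattening signal (a ~5-min peak loses several percent of its
height to a 3-min local-linear window) rather than removing noise, and the
series passes through unchanged. On noisy records the canonical
variable-span behaviour is untouched; with a fixed span no guard applies.

### Calibration

`fitCalibrator()` fits $F_{cal}(t)$ with an order-3 or order-4 polynomial
after subtracting the calibrator's first reading — an instrument-baseline
estimate applied to sample and calibrator alike, so both live on one
fluorescence scale (per-well baselining would erase exactly the spiked-AMC
offset the correction is supposed to confront). `internalLinear()` scales
any rate curve by the single coefficient activity/slope0 — calibration
without artifact correction, which therefore never refuses.
`catCorrect()` inverts the fitted polynomial (root-finding on the monotone
branch — smooth, and faithful to the polynomial-fit formulation) to find
the calibrator time at matched fluorescence, and rescales the sample rate
by activity over the calibrator velocity there. Sample and calibrator at
equal fluorescence sit at the same optical saturation and consumption
state, so both artifacts cancel — within the calibrator's fitted range.

Outside the range the two policies reproduce the two software behaviours:
`refuse` voids the whole well (`no_curve`) when the sample crosses the
calibrator's fluorescence **ceiling** (crossings below the floor are
baseline noise, for which the entry slope is the correct factor — refusing
on them would void every well); `extrapolate` continues along the
polynomial's increasing branch and caps the correction factor at
`max_gain` (default 20) times the linear factor, flagging the curve
`nonphysical` when the cap engages — this is what turns "infinite values"
at deep depletion into finite but flagged output.

### α~2~M subtraction

`subtractAlpha2m()` removes the Tα~2~MG tail by discrete deconvolution
$T_i = E_i - k \sum_{j<i} T_j \Delta t_j$. `auto_k` chooses $k$ so the
final 10% of the record averages zero. The tail mean decreases through
zero near the true rate but creeps back to $0^+$ at large $k$ (the
undershoot transient dies before the tail window), so the solver brackets
the first sign change on a log grid before root-finding; if the tail mean
never crosses zero the closest $k$ is used and flagged. Negative values
are kept in the curve (they carry the noise statistics the amplification
metric needs) and clipped only inside parameter extraction. Subtraction is
performed after correction, before parameter extraction.

### Failure detection and parameters

`detectFailure()` flags curves whose magnitude exceeds 10× the calibrator
activity, that re-ascend after their peak by more than 20% of the peak
(the spurious second peak of full substrate depletion), or whose
detrended tail-to-pre-lag standard-deviation ratio exceeds 5 — the
noise-amplification signature of large correction factors late in the
record. The ratio is always reported; the rule only engages when the tail
variability is material (2% of peak), so noiseless curves are not flagged
on numerically tiny ratios.

`extractParams()` reports TPH (max of the clipped curve), time to peak,
ETP (trapezoidal integral over the full record — no return-to-baseline
detection, matching the fixed 40–60 min windows), and a lag time defined
as the first crossing of max(2 nM, 10% of TPH). The source methodology
never defines lag; the hybrid absolute/fractional rule is robust both for
hemophilic (low-TPH) and normal curves, and both knobs are exposed.

### Normalization and comparison

`normalizeToReference()` divides a test curve (or TPH) by a reference TPH
— the design where hemophilic plasma is read against the same plasma
restored with 1 IU/mL FVIII. In this simulator the IFE multiplies both
arms of such a pair by the same factor, so the normalized ratio is exactly
invariant across spike levels (the measured spread is at machine
precision); real plasma pairs differ optically, so real ratios only
overlap approximately. `pairedCompare()` wraps the paired t test (the
figure-caption convention) with the two-sample variant as an option (the
methods-text convention); the two sources disagree, so both are provided
and neither intent is guessed.

### Edge scans

`runScan()` sweeps one artifact axis (AMC spike, substrate reduction, TF
dose, antithrombin fraction) across methods and replicates, recording
parameters, statuses, and errors against ground truth; each severity
shares one calibrator simulation, matching the paired-well design.
`findSetPoint()` applies a replicate-majority first-failure rule (a single
determination per condition generalises poorly once noise replicates
exist), and `summarizeTable()` labels each method
corrected / overestimated (reported TPH > 1.1× truth) / failed.

## What passing tests do and do not show

The simulator emulates the *mechanisms* — saturating optics,
Michaelis–Menten consumption, a constant-activity calibrator, the
Tα~2~MG tail — under exactly known ground truth. It does not emulate
plasma-to-plasma optical variability, spectral detail of filters and
monochromators, fibrin turbidity, or the proprietary smoothing of
commercial software (whose reported values demonstrably differ from its
own displayed curves). Consequently the scans reproduce the *phenomena and
their ordering* — flat corrected calibrators, refusal above a fluorescence
ceiling, overestimation under extrapolation, erratic tails at depletion —
but not the published numeric set points, which depend on an unpublished
instrument fluorescence scale.

Two quantitative limitations are worth stating plainly. First, with an
unspiked paired calibrator, matched fluorescence implies a *more consumed*
calibrator state by exactly the spike, biasing corrected TPH upward by
roughly $\mathrm{spike}\cdot K_m / (S(S+K_m))$ — about 6–7% at a 102 µM
spike under the defaults, before the refusal ceiling is reached. The
correction is therefore accurate to a few percent at moderate spikes and
degrades smoothly toward the edge, rather than staying exact until
refusal. Second, refusal is driven by the sample's cleaved product
approaching the calibrator ceiling, so the low-signal (hemophilic) arm
refuses *later* than the high-signal arm in this model, whereas commercial
software has been observed to give up earlier on hemophilic samples — its
refusal heuristics are proprietary and out of scope.

## Problem sizes

The shipped tests and the acceptance script run entire plates (10–20
wells × 121 timepoints), severity scans of 3–6 levels × 3–4 methods, and
fine-grid (3 s) wells for the derivative oracles; the whole suite
completes in well under a minute on one core.
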