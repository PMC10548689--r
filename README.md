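# tgedge

Simulation and edge-of-failure analysis of calibrated fluorogenic
thrombin generation (TG) assays.

## The problem

The fluorogenic TG assay reads active thrombin in clotting plasma through
a slow fluorogenic substrate: the first derivative of the fluorescence
record is, ideally, proportional to thrombin concentration. Three effects
bend that proportionality — the inner filter effect (IFE; fluorescence
saturates at high fluorophore load), Michaelis–Menten substrate
depletion, and the residual substrate-cleaving activity of the
thrombin–α2-macroglobulin complex (Tα2MG), which leaves a sloped tail
after free thrombin is gone. The calibrated automated thrombogram (CAT)
method corrects the first two with a parallel calibrator well of known
constant activity, compared to the sample at *matched fluorescence
levels*:

> amidolytic(t) = E_cal × (dF_sample/dt at t) / (dF_cal/dt at t\*),
> where F_cal(t\*) = F_sample(t),

with F_cal fitted by an order-3 or order-4 polynomial. Internal *linear*
calibration instead uses the single coefficient E_cal / slope0 (the
calibrator's initial slope) at every fluorescence level — no artifact
correction, but no way to fail, either. After calibration the Tα2MG tail
is removed by discrete deconvolution T_i = E_i − k·Σ_{j<i} T_j Δt_j, and
the thrombogram is summarized by lag time, time to peak, thrombin peak
height (TPH, nM) and endogenous thrombin potential (ETP, nM·min, area
under the curve).

This package is for assay developers and analysts who need to know *where
those corrections break*: it forward-simulates plates with controllable
artifact severities (spiked AMC fluorophore, reduced substrate, AMC/AFC
substrate mixtures with channel bleed-through, antithrombin-deficient
plasma over a tissue-factor titration), runs four analysis paths
(`linear`, `cat3sg`, `cat4ss`, `cat_strict` — internal linear; CAT with
order-3 polynomial + Savitzky–Golay derivative; CAT with order-4
polynomial + SuperSmoother; CAT that refuses wells leaving the calibrator
range), and scans severity × method grids against known ground truth to
locate each method's edge of failure.

## Worked example

```r
library(tgedge)

# Fig-2-style design: FVIII-restored plasma, AMC spiked at 0 and 102 uM,
# each condition paired with an unspiked calibrator well (noiseless here)
plate <- generatePlate("ife_spike", seed = 1, fviii_levels = 1,
                       amc_spike = c(0, 102), optics = list(noise_sd = 0))
plate
#> TGPlate: 4 wells (2 sample, 2 calibrator), 121 timepoints
#>   time: 0.00..60.00 min (step 0.5 min)
#>   conditions: 2; scenario: ife_spike

analyzeWell(getWell(plate, "S_c01_r1"),
            getWell(plate, "CAL_c01_r1"), "cat3sg")$params
#> TGParams: lag 2 min, ttp 7 min, TPH 154.9 nM, ETP 1472 nM*min (ok)

df <- analyzePlate(plate, methods = c("linear", "cat3sg"))
df[, c("label", "method", "tph", "etp", "status", "tph_rel_err")]
#>                   label method   tph  etp status tph_rel_err
#>    FVIII=1_AMC=0_S0=416 linear 144.2 1373     ok     0.07339
#>    FVIII=1_AMC=0_S0=416 cat3sg 154.9 1472     ok     0.00459
#>  FVIII=1_AMC=102_S0=416 linear  95.9  913     ok     0.38383
#>  FVIII=1_AMC=102_S0=416 cat3sg 166.7 1589     ok     0.07144
```

The simulator's ground truth for these wells is TPH 155.6 nM. Uncorrected
internal linear calibration underestimates it by 7% even with no spike
(substrate consumption alone) and by 38% under a 102 µM spike — the IFE
suppresses the apparent rate, and more so at higher fluorophore load. The
CAT path recovers the peak to 0.5% with no spike and overshoots by 7% at
102 µM, the growing bias that ends, at higher spikes, in refusal
(`cat_strict` returns `no_curve`) or capped, flagged output (`cat3sg`,
`cat4ss`). An edge scan automates exactly this sweep:

```r
rep <- runScan(severityGrid("amc_spike", c(0, 47, 70, 102, 200)),
               methods = c("linear", "cat3sg", "cat_strict"),
               base_scenario = list(optics = list(noise_sd = 0)))
summarizeTable(rep)$summary
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/scripts/tgedge.R simulate -c scenario.yaml -o plate.csv --seed 7
Rscript inst/scripts/tgedge.R analyze plate.csv --method all --out report.json
Rscript inst/scripts/tgedge.R scan -c scan.yaml --out edge.json
```

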