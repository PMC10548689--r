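# shared fixtures; everything generated in code, cached per test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# optics in the linear limit (huge IFE constant), noiseless
linearOptics <- function() opticsParams(ife_K = 1e7, noise_sd = 0)

# linear-regime plate: optics linear and substrate barely consumed, so
# fluorescence rate is proportional to activity throughout
linearRegimePlate <- function(seed = 1) memo("linplate", generatePlate(
  list(scenario = "custom",
       conditions = list(list(substrate_total = 20000, Km = 6000)),
       optics = list(ife_K = 1e7, noise_sd = 0)),
  seed = seed))

# default-conditions noiseless IFE spike plate over the standard AMC grid
ifeSpikePlate <- function(seed = 1) memo("ifeplate", generatePlate(
  "ife_spike", seed = seed, optics = list(noise_sd = 0)))

# brute-force correction oracle: invert the simulator's own optics and
# substrate model to recover amidolytic activity from a noiseless well
# (independent of the calibrator-based correction path)
oracleActivity <- function(well, optics, truth) {
  cond <- well@condition
  f_clean <- well@rfu - optics@dark_offset -
    optics@afc_bleed_coeff * cond@afc_substrate
  phi <- f_clean / optics@gain
  phi <- pmin(phi, optics@ife_K * (1 - 1e-12))
  x <- -optics@ife_K * log(1 - phi / optics@ife_K)   # Phi^{-1}
  P <- x - cond@amc_spike
  S <- cond@substrate_total - P
  dPdt <- tgedge:::centralDiff(well@times, P)
  1000 * dPdt / (cond@kcat * S / (cond@Km + S))      # nM
}

trapz <- function(t, v) sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
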