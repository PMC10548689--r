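test_that("free-thrombin solver matches analytic limits", {
  cm <- conditionMeta(duration = 20, sampling_interval = 15)
  # zero drive -> identically zero
  gt0 <- simulateFreeThrombin(kineticParams(gen_amplitude = 0), cm)
  expect_equal(max(abs(gt0@free_thrombin)), 0)
  expect_equal(max(abs(gt0@a2m_thrombin)), 0)
  expect_equal(max(abs(gt0@amidolytic)), 0)

  # constant drive, no inhibition -> linear growth T = c t
  kp <- kineticParams(k_at = 0, k_a2m = 0)
  gt1 <- simulateFreeThrombin(kp, cm, drive = function(t) rep(5, length(t)))
  expect_equal(gt1@free_thrombin, 5 * gt1@times, tolerance = 1e-6)

  # constant drive, total decay k -> T = (c/k)(1 - exp(-k t))
  kp2 <- kineticParams(k_at = 0.3, at_fraction = 1, heparin_factor = 1,
                       k_a2m = 0.1)
  gt2 <- simulateFreeThrombin(kp2, cm, drive = function(t) rep(8, length(t)))
  k <- 0.3 + 0.1
  closed <- (8 / k) * (1 - exp(-k * gt2@times))
  expect_lt(max(abs(gt2@free_thrombin - closed)[-1] / closed[-1]), 1e-4)
})

test_that("thrombin pulse scales with FVIII and tissue factor dose", {
  cm1 <- conditionMeta(fviii_level = 1)
  cm0 <- conditionMeta(fviii_level = 0)
  kp <- kineticParams()
  t1 <- max(simulateFreeThrombin(kp, cm1)@free_thrombin)
  t0 <- max(simulateFreeThrombin(kp, cm0)@free_thrombin)
  expect_lt(t0, 0.15 * t1)     # severe hemophilia: small residual peak
  # higher TF: bigger amplitude, earlier onset
  hi <- simulateFreeThrombin(kineticParams(tf_pM = 20), cm1)
  lo <- simulateFreeThrombin(kineticParams(tf_pM = 0.5), cm1)
  expect_gt(max(hi@free_thrombin), max(lo@free_thrombin))
  thr <- 0.1 * max(lo@free_thrombin)
  expect_lt(hi@times[which(hi@free_thrombin > thr)[1]],
            lo@times[which(lo@free_thrombin > thr)[1]])
})

test_that("fluorescence model honours its closed-form limits", {
  cm <- conditionMeta(amc_spike = 0, sampling_interval = 30, duration = 30)
  op <- opticsParams(noise_sd = 0)
  times <- tgedge:::timeGrid(cm)
  zero <- new("GroundTruth", times = times,
              free_thrombin = rep(0, length(times)),
              a2m_thrombin = rep(0, length(times)),
              amidolytic = rep(0, length(times)),
              substrate = numeric(0), product = numeric(0))
  # dead well: flat at the dark offset
  w <- simulateFluorescence(zero, op, cm)
  expect_equal(w@rfu, rep(op@dark_offset, length(times)))

  # first-order limit: Km >> S0, constant E, near-linear optics:
  # S = S0 exp(-(kcat/Km) E t), F - dark = gain (S0 - S)
  cmf <- conditionMeta(substrate_total = 10, Km = 5000, kcat = 54,
                       duration = 30)
  opf <- opticsParams(ife_K = 1e9, noise_sd = 0)
  Ec <- 200
  const <- new("GroundTruth", times = times,
               free_thrombin = rep(0, length(times)),
               a2m_thrombin = rep(Ec, length(times)),
               amidolytic = rep(Ec, length(times)),
               substrate = numeric(0), product = numeric(0))
  wf <- simulateFluorescence(const, opf, cmf, return_truth = TRUE)
  S_closed <- 10 * exp(-(54 / 5000) * (Ec / 1000) * times)
  F_closed <- opf@dark_offset + opf@gain * (10 - S_closed)
  rel <- abs(wf$well@rfu - F_closed) / (opf@gain * 10)
  expect_lt(max(rel), 1e-3)
})

test_that("baseline fluorescence rises sub-linearly with spiked AMC", {
  spikes <- c(0, 47, 70, 102, 200)
  cm <- conditionMeta(substrate_total = 416)
  op <- opticsParams(noise_sd = 0)
  f0 <- vapply(spikes, function(sp) {
    cmi <- conditionMeta(amc_spike = sp)
    times <- tgedge:::timeGrid(cmi)
    zero <- new("GroundTruth", times = times,
                free_thrombin = rep(0, length(times)),
                a2m_thrombin = rep(0, length(times)),
                amidolytic = rep(0, length(times)),
                substrate = numeric(0), product = numeric(0))
    simulateFluorescence(zero, op, cmi)@rfu[1]
  }, numeric(1))
  expect_true(all(diff(f0) > 0))            # strictly increasing
  # concave: increments per uM shrink with the spike level
  slopes <- diff(f0) / diff(spikes)
  expect_true(all(diff(slopes) < 0))
})

test_that("IFE transform is increasing, concave and bounded by identity", {
  x <- seq(0, 600, by = 1.7)
  K <- 250
  phi <- ifePhi(x, K)
  expect_true(all(diff(phi) > 0))
  expect_true(all(diff(diff(phi)) < 0))
  expect_true(all(phi[-1] < x[-1]))
  expect_equal(ifePhi(0, K), 0)
  # linear limit
  expect_equal(ifePhi(x, 1e9), x, tolerance = 1e-6)
})

test_that("calibrator wells behave as the optical model predicts", {
  # near-linear regime: straight line with R^2 > 0.999
  cml <- conditionMeta(substrate_total = 20000, Km = 6000)
  opl <- linearOptics()
  wl <- makeCalibratorWell(opl, cml)
  fit <- summary(lm(wl@rfu ~ wl@times))
  expect_gt(fit$r.squared, 0.999)

  # finite IFE: apparent rate strictly decreasing (noiseless)
  cmn <- conditionMeta()
  opn <- opticsParams(noise_sd = 0)
  wn <- makeCalibratorWell(opn, cmn)
  rate <- tgedge:::centralDiff(wn@times, wn@rfu)
  expect_true(all(diff(rate[-1]) < 0))

  # an AMC-spiked sample baseline lowers the apparent initial slope
  # (evaluate Phi' at the two baselines)
  times <- tgedge:::timeGrid(cmn)
  e <- rep(cmn@calibrator_activity, length(times))
  truth <- new("GroundTruth", times = times,
               free_thrombin = rep(0, length(times)), a2m_thrombin = e,
               amidolytic = e, substrate = numeric(0), product = numeric(0))
  spiked <- simulateFluorescence(truth, opn, conditionMeta(amc_spike = 150))
  expect_gt(spiked@rfu[1], wn@rfu[1])
  r_sp <- tgedge:::centralDiff(spiked@times, spiked@rfu)
  expect_lt(r_sp[1], rate[1])
})

test_that("generate_plate: design coverage, conservation, determinism", {
  plate <- ifeSpikePlate()
  cd <- SummarizedExperiment::colData(plate)
  # Fig-2-like design: 2 plasma states x 5 spikes + paired calibrators
  expect_equal(sum(cd$role == "sample"), 10)
  expect_equal(sum(cd$role == "calibrator"), 10)
  expect_equal(length(metadata(plate)$conditions), 10)
  for (ci in unique(cd$condition_id[cd$role == "sample"]))
    expect_gte(length(calibratorFor(plate, ci)), 1)

  # substrate conservation on every well
  for (wid in wellIds(plate)) {
    g <- groundTruth(plate, wid)
    s0 <- g@substrate[1] + g@product[1]
    expect_lt(max(abs(g@substrate + g@product - s0)) / s0, 1e-9)
    expect_true(all(diff(g@product) >= -1e-12))
    expect_true(all(diff(g@a2m_thrombin) >= -1e-12))
  }

  # determinism: same seed twice -> identical plates
  p1 <- generatePlate("ife_spike", seed = 42, fviii_levels = 1,
                      amc_spike = c(0, 102))
  p2 <- generatePlate("ife_spike", seed = 42, fviii_levels = 1,
                      amc_spike = c(0, 102))
  expect_identical(assay(p1, "rfu"), assay(p2, "rfu"))

  # noiseless F non-decreasing when E >= 0
  noiseless <- ifeSpikePlate()
  for (wid in wellIds(noiseless)[1:4])
    expect_true(all(diff(getWell(noiseless, wid)@rfu) >= -1e-9))

  # a2M tail: terminal slope stays positive while substrate remains
  w <- getWell(noiseless, "S_c06_r1")   # FVIII=1, no spike
  n <- length(w@times)
  expect_gt(w@rfu[n] - w@rfu[n - 1], 0)
})

test_that("substrate_reduction calibrators carry the matching S0", {
  plate <- generatePlate("substrate_reduction", seed = 5,
                         optics = list(noise_sd = 0))
  ct <- conditionTable(plate)
  expect_equal(max(ct$substrate_total) / min(ct$substrate_total), 20,
               tolerance = 0.01)
  for (ci in ct$condition_id) {
    cal_id <- calibratorFor(plate, ci)[1]
    expect_equal(getWell(plate, cal_id)@condition@substrate_total,
                 metadata(plate)$conditions[[ci]]@substrate_total)
  }
})

test_that("ground-truth activity is recoverable by brute-force inversion", {
  # fine sampling so the numerical derivative in the inversion oracle is
  # negligible against the 1e-3 recovery tolerance
  plate <- generatePlate(list(
    scenario = "custom",
    conditions = list(list(amc_spike = 47, sampling_interval = 3,
                           duration = 30)),
    optics = list(noise_sd = 0)), seed = 9)
  w <- getWell(plate, "S_c01_r1")
  gt <- groundTruth(plate, "S_c01_r1")
  est <- oracleActivity(w, opticsParams(noise_sd = 0), gt)
  keep <- gt@amidolytic > 0.05 * max(gt@amidolytic)
  keep[c(1, length(keep))] <- FALSE      # one-sided ends are O(h)
  rel <- abs(est - gt@amidolytic)[keep] / max(gt@amidolytic)
  expect_lt(max(rel), 1e-3)
})

test_that("unknown scenarios and missing pieces are rejected", {
  expect_error(generatePlate("no_such_scenario", seed = 1), "unknown")
  expect_error(generatePlate(list(scenario = "custom"), seed = 1),
               "conditions")
  expect_error(simulateFreeThrombin(kineticParams(gen_tau = -1),
                                    conditionMeta()), "gen_tau")
  expect_error(makeCalibratorWell(opticsParams(),
                                  conditionMeta(calibrator_activity = 0)),
               "calibrator_activity")
})
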