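mkWell <- function(times, rfu, role = "calibrator", cond = conditionMeta()) {
  new("TGWell", well_id = "W", role = role, condition_id = "c1",
      condition = cond, times = times, rfu = rfu)
}

test_that("calibrator fitting recovers linear and saturating slopes", {
  t <- seq(0, 60, by = 0.5)
  lin <- mkWell(t, 120 * t + 80)
  calL <- fitCalibrator(lin, 3)
  expect_equal(calL@slope0, 120, tolerance = 1e-6)
  expect_lt(max(abs(calL@coeffs[3:4])), 1e-6)
  expect_equal(calL@baseline, 80)

  # simulated saturating calibrator: fitted slope0 within 2% of the
  # analytic initial slope gain * Phi'(0) * dx/dt(0)
  cm <- conditionMeta()
  op <- opticsParams(noise_sd = 0)
  cw <- makeCalibratorWell(op, cm)
  v0 <- op@gain * cm@kcat * (cm@calibrator_activity / 1000) *
    cm@substrate_total / (cm@Km + cm@substrate_total)
  for (ord in c(3, 4)) {
    cal <- fitCalibrator(cw, ord)
    expect_equal(cal@slope0, v0, tolerance = 0.02)
  }
  # nested models: order-4 residual cannot exceed order-3 residual
  y <- cw@rfu - cw@rfu[1]
  r3 <- sum(resid(lm(y ~ poly(t, 3, raw = TRUE)))^2)
  r4 <- sum(resid(lm(y ~ poly(t, 4, raw = TRUE)))^2)
  expect_lte(r4, r3)

  expect_error(fitCalibrator(mkWell(t, 120 * t, role = "sample")),
               "calibrator role")
  expect_error(fitCalibrator(mkWell(t, 100 - t)), "not increasing")
})

test_that("internal linear calibration is a single-coefficient scaling", {
  t <- seq(0, 60, by = 0.5)
  cal <- fitCalibrator(mkWell(t, 120 * t), 3, activity = 100)
  rc <- new("RateCurve", times = t, rate = rep(120, length(t)),
            smoother_used = smootherSpec("none"))
  ac <- internalLinear(rc, cal)
  expect_equal(ac@amidolytic, rep(100, length(t)), tolerance = 1e-6)
  rc0 <- new("RateCurve", times = t, rate = rep(0, length(t)),
             smoother_used = smootherSpec("none"))
  expect_equal(internalLinear(rc0, cal)@amidolytic, rep(0, length(t)))
})

test_that("internal linear TPH falls monotonically with spiked AMC", {
  plate <- ifeSpikePlate()
  df <- analyzePlate(plate, methods = "linear")
  for (fv in c(0, 1)) {
    sub <- df[grepl(sprintf("FVIII=%d_", fv), df$label), ]
    sub <- sub[order(as.numeric(sub("^.*AMC=([0-9]+).*$", "\\1",
                                    sub$label))), ]
    expect_true(all(diff(sub$tph) < 0),
                label = sprintf("monotone IFE suppression, FVIII=%d", fv))
  }
})

test_that("CAT correction matches internal linear in the no-artifact limit", {
  plate <- linearRegimePlate()
  sw <- getWell(plate, "S_c01_r1")
  cw <- getWell(plate, "CAL_c01_r1")
  cal <- fitCalibrator(cw, 3)
  spec <- correctionSpec(3, smootherSpec("none"), "extrapolate")
  ac_cat <- catCorrect(sw, cal, spec)
  ac_lin <- internalLinear(differentiate(sw, smootherSpec("none")), cal)
  keep <- ac_lin@amidolytic > 0.05 * max(ac_lin@amidolytic)
  rel <- abs(ac_cat@amidolytic - ac_lin@amidolytic)[keep] /
    max(ac_lin@amidolytic)
  expect_lt(max(rel), 0.01)
})

test_that("corrected calibrator flat-lines while uncorrected declines", {
  cm <- conditionMeta()
  op <- opticsParams(noise_sd = 0)
  cw <- makeCalibratorWell(op, cm)
  cal <- fitCalibrator(cw, 3)
  ac <- catCorrect(cw, cal, correctionSpec(3, smootherSpec("none"),
                                           "extrapolate"))
  # flat within 2% of the assigned activity over the window interior
  # (the outermost points carry the polynomial's edge wiggle and the
  # one-sided derivative)
  inner <- cw@times > 2 & cw@times < 58
  expect_lt(max(abs(ac@amidolytic[inner] - cm@calibrator_activity)) /
              cm@calibrator_activity, 0.02)
  # order 4 absorbs the residual curvature almost completely
  cal4 <- fitCalibrator(cw, 4)
  ac4 <- catCorrect(cw, cal4, correctionSpec(4, smootherSpec("none"),
                                             "extrapolate"))
  expect_lt(max(abs(ac4@amidolytic[inner] - cm@calibrator_activity)) /
              cm@calibrator_activity, 0.005)
  # slope statistically zero (noiseless flat-line property)
  sl <- coef(lm(ac@amidolytic[inner] ~ cw@times[inner]))[2]
  expect_lt(abs(sl), 1e-3 * cm@calibrator_activity)
  # uncorrected: apparent activity declines from t = 0
  un <- internalLinear(differentiate(cw, smootherSpec("none")), cal)
  expect_true(all(diff(un@amidolytic[-1]) < 1e-9))
  expect_lt(un@amidolytic[sum(inner)], 0.8 * un@amidolytic[2])
})

test_that("CAT correction recovers simulated ground truth within range", {
  plate <- generatePlate("ife_spike", seed = 2, fviii_levels = 1,
                         amc_spike = 47, optics = list(noise_sd = 0))
  sw <- getWell(plate, "S_c01_r1")
  cw <- getWell(plate, "CAL_c01_r1")
  gt <- groundTruth(plate, "S_c01_r1")
  cal <- fitCalibrator(cw, 3)
  ac <- catCorrect(sw, cal, correctionSpec(3, smootherSpec("none"),
                                           "extrapolate"))
  expect_equal(statusCode(ac), "ok")
  rmse <- sqrt(mean((ac@amidolytic - gt@amidolytic)^2))
  expect_lt(rmse / max(gt@amidolytic), 0.03)

  # oracle equivalence: agrees with the brute-force inversion of the
  # simulator's own optics/substrate model
  est <- oracleActivity(sw, opticsParams(noise_sd = 0), gt)
  inner <- 3:(length(est) - 3)
  expect_lt(sqrt(mean((ac@amidolytic - est)[inner]^2)) /
              max(gt@amidolytic), 0.03)
})

test_that("refuse policy voids wells crossing the calibrator ceiling", {
  plate <- ifeSpikePlate()
  spec <- correctionSpec(3, smootherSpec("none"), "refuse")
  # FVIII=1 conditions are c06..c10 with spikes 0,47,70,102,200
  codes <- vapply(sprintf("c%02d", 6:10), function(ci) {
    sw <- getWell(plate, sprintf("S_%s_r1", ci))
    cal <- fitCalibrator(getWell(plate, sprintf("CAL_%s_r1", ci)), 3)
    statusCode(catCorrect(sw, cal, spec))
  }, character(1))
  expect_true("no_curve" %in% codes)
  # edge monotonicity: once a spike fails, all larger spikes fail
  failed <- codes == "no_curve"
  expect_true(all(failed[which(failed)[1]:length(failed)]))
  # the first refusal matches the independent fluorescence-ceiling oracle
  oracle_fail <- vapply(sprintf("c%02d", 6:10), function(ci) {
    sw <- getWell(plate, sprintf("S_%s_r1", ci))
    cw <- getWell(plate, sprintf("CAL_%s_r1", ci))
    any(sw@rfu - cw@rfu[1] > max(cw@rfu - cw@rfu[1]))
  }, logical(1))
  expect_equal(unname(failed), unname(oracle_fail))
})

test_that("a2M deconvolution inverts its forward construction", {
  t <- seq(0, 60, by = 0.5)
  T_true <- 150 * (t / 3)^2 * exp(-t / 3)
  k_true <- 0.04
  # forward construction with the same running-sum quadrature
  cum <- c(0, cumsum(T_true[-length(t)] * diff(t)))
  E <- T_true + k_true * cum
  ac <- new("ActivityCurve", times = t, amidolytic = E,
            status = failureStatus(), correction_factor = numeric(0),
            method = "linear")
  # identity at k = 0
  tc0 <- subtractAlpha2m(ac, "fixed_k", k = 0)
  expect_equal(tc0@free_thrombin, E)
  # exact inversion at the true rate
  tcf <- subtractAlpha2m(ac, "fixed_k", k = k_true)
  expect_lt(max(abs(tcf@free_thrombin - T_true)) / max(T_true), 1e-6)
  # auto-k recovery
  tca <- subtractAlpha2m(ac, "auto_k")
  expect_equal(tca@k_a2m_used, k_true, tolerance = 0.05)
  n <- length(t)
  tail_idx <- t >= 54
  expect_lt(abs(mean(tca@free_thrombin[tail_idx])), 0.005 * max(T_true))
  # infeasible tail: negative tail mean at k = 0 falls back with warning
  acneg <- new("ActivityCurve", times = t, amidolytic = -E,
               status = failureStatus(), correction_factor = numeric(0),
               method = "linear")
  tcn <- subtractAlpha2m(acneg, "auto_k")
  expect_equal(statusCode(tcn), "nonphysical")
  expect_equal(tcn@k_a2m_used, 0)
})

test_that("failure detection flags the depletion artifacts", {
  t <- seq(0, 60, by = 0.5)
  pulse <- 150 * (t / 3)^2 * exp(-t / 3)
  clean <- new("ThrombinCurve", times = t, free_thrombin = pulse,
               k_a2m_used = 0, status = failureStatus())
  expect_equal(statusCode(detectFailure(clean, activity = 100)), "ok")
  # runaway values beyond the cap
  expect_equal(statusCode(detectFailure(
    new("ThrombinCurve", times = t, free_thrombin = pulse * 20,
        k_a2m_used = 0, status = failureStatus()), activity = 100)),
    "nonphysical")
  # tail re-ascent (second-peak artifact)
  re <- pulse + ifelse(t > 40, 60 * (t - 40) / 20, 0)
  expect_equal(statusCode(detectFailure(
    new("ThrombinCurve", times = t, free_thrombin = re, k_a2m_used = 0,
        status = failureStatus()), activity = 100)), "nonphysical")
  # no_curve propagates
  nc <- new("ThrombinCurve", times = t,
            free_thrombin = rep(NA_real_, length(t)), k_a2m_used = 0,
            status = failureStatus("no_curve", "upstream"))
  expect_equal(statusCode(detectFailure(nc, activity = 100)), "no_curve")
  # noise amplification ratio reported
  set.seed(8)
  noisy <- pulse + rnorm(length(t), 0, 1) * ifelse(t > 50, 25, 1)
  st <- detectFailure(new("ThrombinCurve", times = t,
                          free_thrombin = noisy, k_a2m_used = 0,
                          status = failureStatus()), activity = 100)
  expect_equal(st@code, "nonphysical")
  expect_gt(st@noise_amplification, 5)
})

test_that("calibrated outputs are gauge-invariant under RFU rescaling", {
  for (gain_mult in c(3.7)) {
    p1 <- generatePlate("ife_spike", seed = 4, fviii_levels = 1,
                        amc_spike = 47, optics = list(noise_sd = 0))
    sw <- getWell(p1, "S_c01_r1"); cw <- getWell(p1, "CAL_c01_r1")
    scale_well <- function(w, c) { w@rfu <- w@rfu * c; w }
    sw2 <- scale_well(sw, gain_mult); cw2 <- scale_well(cw, gain_mult)
    for (m in c("linear", "cat3sg")) {
      a1 <- analyzeWell(sw, cw, m)$activity@amidolytic
      a2 <- analyzeWell(sw2, cw2, m)$activity@amidolytic
      expect_equal(a1, a2, tolerance = 1e-9,
                   label = sprintf("gauge invariance, %s", m))
    }
  }
})
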