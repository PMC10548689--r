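test_that("scan covers the full severity x method grid deterministically", {
  grid <- severityGrid("amc_spike", c(0, 47, 70, 102, 200))
  base <- list(optics = list(noise_sd = 0),
               conditions = NULL)
  rep1 <- runScan(grid, methods = c("linear", "cat3sg", "cat4ss",
                                    "cat_strict"), base_scenario = base)
  expect_equal(nrow(rep1$cells), 5 * 4)
  expect_equal(nrow(unique(rep1$cells[c("severity", "method")])), 20)
  rep2 <- runScan(grid, methods = c("linear", "cat3sg", "cat4ss",
                                    "cat_strict"), base_scenario = base)
  expect_identical(rep1$cells, rep2$cells)
})

test_that("no-artifact scan is clean with small parameter error", {
  grid <- severityGrid("amc_spike", c(0, 1))
  base <- list(optics = list(ife_K = 1e7, noise_sd = 0),
               condition = list(substrate_total = 20000, Km = 6000))
  rep <- runScan(grid, methods = c("linear", "cat3sg", "cat_strict"),
                 base_scenario = base)
  expect_true(all(rep$cells$status == "ok"))
  expect_lt(max(rep$cells$tph_rel_err), 0.02)
  expect_true(all(is.na(rep$set_points$value)))
})

test_that("refuse-policy set point equals the fluorescence-ceiling oracle", {
  spikes <- c(0, 47, 70, 102, 150, 200)
  grid <- severityGrid("amc_spike", spikes)
  base <- list(optics = list(noise_sd = 0))
  rep <- runScan(grid, methods = "cat_strict", base_scenario = base)
  sp <- findSetPoint(rep, "cat_strict")
  expect_equal(sp$basis, "no_curve")

  # oracle: first spike whose simulated fluorescence crosses the paired
  # calibrator's observed maximum, computed from the plates alone
  oracle <- NA_real_
  for (v in spikes) {
    plate <- generatePlate(list(
      scenario = "custom", conditions = list(list(amc_spike = v)),
      optics = list(noise_sd = 0)), seed = 1)
    sw <- getWell(plate, "S_c01_r1")
    cw <- getWell(plate, "CAL_c01_r1")
    if (any(sw@rfu - cw@rfu[1] > max(cw@rfu - cw@rfu[1]))) {
      oracle <- v; break
    }
  }
  expect_equal(sp$value, oracle)

  # failure upper-set property along the severity axis
  st_by_sev <- vapply(spikes, function(v)
    all(rep$cells$status[rep$cells$severity == v] != "ok"), logical(1))
  first_fail <- which(st_by_sev)[1]
  expect_true(all(st_by_sev[first_fail:length(st_by_sev)]))
})

test_that("first-failure rule picks the first majority-failing severity", {
  cells <- data.frame(
    severity = rep(c(1, 2, 3, 4), each = 1), replicate = 1,
    method = "cat_strict",
    status = c("ok", "ok", "nonphysical", "no_curve"),
    tph = 1, tph_true = 1, tph_rel_err = 0,
    stringsAsFactors = FALSE)
  rep <- structure(list(
    grid = severityGrid("amc_spike", c(1, 2, 3, 4)),
    cells = cells, set_points = NULL), class = "EdgeReport")
  sp <- findSetPoint(rep, "cat_strict")
  expect_equal(sp$value, 3)
  expect_equal(sp$basis, "nonphysical")
  expect_error(findSetPoint(rep, "linear"), "absent")
})

test_that("ATIII-deficiency scan fails as an upper set along TF", {
  grid <- severityGrid("tf_pM", c(0.12, 2, 20))
  base <- list(condition = list(substrate_total = 800),
               kinetics = list(at_fraction = 0.05),
               optics = list(noise_sd = 0))
  rep <- runScan(grid, methods = c("cat3sg", "cat4ss", "cat_strict"),
                 base_scenario = base)
  # full depletion at the top dose flags every CAT variant
  top <- rep$cells[rep$cells$severity == 20, ]
  expect_true(all(top$status %in% c("nonphysical", "no_curve")))
  # upper-set property per method
  for (m in unique(rep$cells$method)) {
    cm <- rep$cells[rep$cells$method == m, ]
    bad <- vapply(grid$values, function(v)
      any(cm$status[cm$severity == v] != "ok"), logical(1))
    if (any(bad))
      expect_true(all(bad[which(bad)[1]:length(bad)]),
                  label = sprintf("upper set along TF, %s", m))
  }
})

test_that("summary table labels corrected / overestimated / failed", {
  grid <- severityGrid("amc_spike", c(0, 47, 200))
  base <- list(optics = list(noise_sd = 0))
  rep <- runScan(grid, methods = c("cat3sg", "cat_strict"),
                 base_scenario = base)
  doc <- summarizeTable(rep)
  expect_s3_class(doc, "ReportDoc")
  expect_equal(nrow(doc$summary), 2)
  s3 <- doc$summary[doc$summary$method == "cat3sg", ]
  strict <- doc$summary[doc$summary$method == "cat_strict", ]
  expect_equal(s3$outcome, "overestimated")    # clamped beyond the range
  expect_equal(strict$outcome, "failed")       # refusal at the top spike
  expect_true(is.finite(s3$max_severity_within_10pct))
  # serializes
  path <- tempfile(fileext = ".json")
  writeReport(doc, path, "json")
  expect_true(file.exists(path))
  unlink(path)
})
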