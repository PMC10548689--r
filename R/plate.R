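#' Assemble a TGPlate from wells
#'
#' All wells must share one time grid. Sample conditions must each have at
#' least one paired calibrator well.
#'
#' @param wells list of [TGWell-class].
#' @param conditions named list of [ConditionMeta-class], keyed by
#'   condition id.
#' @param pairing named list: sample condition id -> character vector of
#'   calibrator well ids.
#' @param ground_truth optional named list of [GroundTruth-class] per well.
#' @param scenario scenario name stored in metadata.
#' @param seed run seed stored in metadata.
#' @return A [TGPlate-class].
#' @export
newTGPlate <- function(wells, conditions, pairing, ground_truth = NULL,
                       scenario = NULL, seed = NULL) {
  stopifnot(length(wells) >= 1)
  times <- wells[[1]]@times
  for (w in wells)
    if (length(w@times) != length(times) ||
        max(abs(w@times - times)) > 1e-9)
      stop(sprintf("well '%s' is not on the shared time grid", w@well_id))
  ids <- unname(vapply(wells, function(w) w@well_id, character(1)))
  if (anyDuplicated(ids))
    stop(sprintf("duplicated well_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  m <- vapply(wells, function(w) w@rfu, numeric(length(times)))
  colnames(m) <- ids
  cd <- S4Vectors::DataFrame(
    well_id = ids,
    role = vapply(wells, function(w) w@role, character(1)),
    condition_id = vapply(wells, function(w) w@condition_id, character(1)),
    row.names = ids)
  se <- SummarizedExperiment(
    assays = list(rfu = m),
    rowData = S4Vectors::DataFrame(time_min = times),
    colData = cd)
  metadata(se) <- list(pairing = pairing, conditions = conditions,
                       ground_truth = ground_truth, scenario = scenario,
                       seed = seed)
  out <- new("TGPlate", se)
  validObject(out)
  out
}

## deterministic per-well sub-seed stream, kept below 2^31
wellSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647L)
}

defaultScenarioConditions <- function(name, opts) {
  get0 <- function(key, default) {
    v <- opts[[key]]
    if (is.null(v)) default else v
  }
  base <- get0("condition", list())
  mkcond <- function(...) do.call(conditionMeta, utils::modifyList(base, list(...)))
  switch(name,
    ife_spike = {
      spikes <- get0("amc_spike", c(0, 47, 70, 102, 200))
      fviii <- get0("fviii_levels", c(0, 1))
      conds <- list()
      for (fv in fviii) for (sp in spikes)
        conds[[length(conds) + 1L]] <- mkcond(fviii_level = fv,
                                              amc_spike = sp)
      conds
    },
    substrate_reduction = {
      s0 <- get0("substrate_total",
                 round(416 * c(1, 1 / 2, 1 / 4, 1 / 10, 1 / 20), 1))
      lapply(s0, function(s) mkcond(substrate_total = s))
    },
    amc_afc_mixture = {
      afc <- get0("afc_substrate", c(0, 200, 400, 600, 700, 750, 800))
      total <- get0("total_substrate", 800)
      lapply(afc, function(a) mkcond(substrate_total = total - a,
                                     afc_substrate = a))
    },
    atiii_procoagulant = {
      tf <- get0("tf_pM", c(0.12, 0.5, 2, 5, 20))
      lapply(tf, function(x) mkcond(substrate_total = get0("s0", 800),
                                    label = sprintf("ATIII-DP_TF=%gpM", x)))
    },
    custom = {
      cl <- opts[["conditions"]]
      if (is.null(cl) || !length(cl))
        stop("custom scenario requires a 'conditions' list")
      lapply(cl, function(co)
        if (is(co, "ConditionMeta")) co else do.call(conditionMeta, co))
    },
    stop(sprintf("unknown scenario '%s'", name))
  )
}

#' Generate a synthetic fluorogenic TG plate
#'
#' Forward-simulates sample and calibrator wells for one of the built-in
#' forced-artifact scenarios (or a custom condition list), retaining the
#' ground truth for every well. Deterministic for a given seed.
#'
#' Scenarios:
#' \describe{
#'   \item{ife_spike}{AMC spiked into plasma at 0-200 uM over two plasma
#'     states (FVIII 0 and 1 IU/mL); induces the inner filter effect.}
#'   \item{substrate_reduction}{ZGGR-AMC reduced up to 20-fold from the
#'     commercial 416 uM; calibrators carry the matching S0.}
#'   \item{amc_afc_mixture}{AMC/AFC substrate mixtures summing to 800 uM;
#'     AFC bleeds into the AMC channel.}
#'   \item{atiii_procoagulant}{antithrombin-depleted plasma (5% of normal
#'     antithrombin) with a tissue-factor titration and optional heparin;
#'     drives deep substrate depletion.}
#'   \item{custom}{explicit condition list.}
#' }
#'
#' @param scenario scenario name, or a list with elements \code{scenario},
#'   optional \code{kinetics}/\code{optics} (parameter overrides or
#'   objects), optional scenario options (see above), \code{replicates},
#'   \code{calibrator_replicates}, \code{early_drop_amp}.
#' @param seed integer run seed.
#' @param ... scenario options passed when \code{scenario} is a name.
#' @return A [TGPlate-class] with ground truth in \code{metadata}.
#' @examples
#' plate <- generatePlate("ife_spike", seed = 1,
#'                        optics = list(noise_sd = 0),
#'                        fviii_levels = 1, amc_spike = c(0, 102))
#' plate
#' @export
generatePlate <- function(scenario, seed = 1L, ...) {
  opts <- if (is.list(scenario)) scenario else c(list(scenario = scenario),
                                                 list(...))
  name <- opts$scenario
  if (is.null(name)) stop("scenario name is required")
  kin <- opts$kinetics
  if (is.null(kin)) kin <- kineticParams()
  else if (!is(kin, "KineticParams")) kin <- do.call(kineticParams, kin)
  if (name == "atiii_procoagulant") {
    # antithrombin-deficient plasma reconstituted with 5% normal plasma
    if (is.null(opts$kinetics$at_fraction)) kin@at_fraction <- 0.05
    if (isTRUE(opts$heparin) && is.null(opts$kinetics$heparin_factor))
      kin@heparin_factor <- 4
  }
  opt <- opts$optics
  if (is.null(opt)) opt <- opticsParams()
  else if (!is(opt, "OpticsParams")) opt <- do.call(opticsParams, opt)

  conds <- defaultScenarioConditions(name, opts)
  names(conds) <- sprintf("c%02d", seq_along(conds))
  reps <- if (is.null(opts$replicates)) 1L else as.integer(opts$replicates)
  creps <- if (is.null(opts$calibrator_replicates)) 1L
           else as.integer(opts$calibrator_replicates)
  if (reps < 1) stop("replicate count must be >= 1")
  drop_amp <- if (is.null(opts$early_drop_amp)) 0 else opts$early_drop_amp

  wells <- list(); truths <- list(); pairing <- list()
  idx <- 0L
  for (ci in names(conds)) {
    cm <- conds[[ci]]
    kin_c <- kin
    if (name == "atiii_procoagulant" && grepl("TF=", cm@label))
      kin_c@tf_pM <- as.numeric(sub(".*TF=([0-9.]+)pM.*", "\\1", cm@label))
    for (r in seq_len(reps)) {
      idx <- idx + 1L
      wid <- sprintf("S_%s_r%d", ci, r)
      gt <- simulateFreeThrombin(kin_c, cm)
      sim <- simulateFluorescence(gt, opt, cm, seed = wellSeed(seed, idx),
                                  well_id = wid, role = "sample",
                                  condition_id = ci,
                                  early_drop_amp = drop_amp,
                                  return_truth = TRUE)
      wells[[wid]] <- sim$well
      truths[[wid]] <- sim$truth
    }
    cal_ids <- character(0)
    for (r in seq_len(creps)) {
      idx <- idx + 1L
      wid <- sprintf("CAL_%s_r%d", ci, r)
      sim <- makeCalibratorWell(opt, cm, seed = wellSeed(seed, idx),
                                well_id = wid, condition_id = ci,
                                early_drop_amp = drop_amp,
                                return_truth = TRUE)
      wells[[wid]] <- sim$well
      truths[[wid]] <- sim$truth
      cal_ids <- c(cal_ids, wid)
    }
    pairing[[ci]] <- cal_ids
  }
  newTGPlate(wells, conds, pairing, ground_truth = truths,
             scenario = name, seed = seed)
}
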