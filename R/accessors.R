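#' Accessors for TGPlate and curve objects
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x a [TGPlate-class], [TGWell-class] or curve object as
#'   documented per function.
#' @name accessors
NULL

#' @describeIn accessors time grid of a plate, min.
#' @export
plateTimes <- function(x) {
  stopifnot(is(x, "TGPlate"))
  rowData(x)$time_min
}

#' @describeIn accessors well identifiers of a plate.
#' @export
wellIds <- function(x) {
  stopifnot(is(x, "TGPlate"))
  colData(x)$well_id
}

#' @describeIn accessors well roles (sample/calibrator), named by well id.
#' @export
wellRoles <- function(x) {
  stopifnot(is(x, "TGPlate"))
  stats::setNames(colData(x)$role, colData(x)$well_id)
}

#' Extract one well from a plate
#'
#' @param x a [TGPlate-class].
#' @param well_id the well identifier.
#' @return A [TGWell-class] carrying the well's time series and condition.
#' @export
getWell <- function(x, well_id) {
  stopifnot(is(x, "TGPlate"))
  i <- match(well_id, colData(x)$well_id)
  if (is.na(i)) stop(sprintf("no well '%s' on this plate", well_id))
  cond <- metadata(x)$conditions[[colData(x)$condition_id[i]]]
  if (is.null(cond)) cond <- conditionMeta()
  new("TGWell", well_id = well_id, role = colData(x)$role[i],
      condition_id = colData(x)$condition_id[i], condition = cond,
      times = plateTimes(x), rfu = as.numeric(assay(x, "rfu")[, i]))
}

#' Calibrator wells paired with a sample condition
#'
#' @param x a [TGPlate-class].
#' @param condition_id the sample condition identifier.
#' @return Character vector of calibrator well ids.
#' @export
calibratorFor <- function(x, condition_id) {
  stopifnot(is(x, "TGPlate"))
  cal <- metadata(x)$pairing[[condition_id]]
  if (is.null(cal))
    stop(sprintf("no calibrator paired with condition '%s'", condition_id))
  cal
}

#' Ground truth retained for a simulated well
#'
#' @param x a [TGPlate-class].
#' @param well_id the well identifier.
#' @return A [GroundTruth-class], or NULL when the plate was not simulated.
#' @export
groundTruth <- function(x, well_id) {
  stopifnot(is(x, "TGPlate"))
  metadata(x)$ground_truth[[well_id]]
}

#' Condition table of a plate
#'
#' @param x a [TGPlate-class].
#' @return data.frame with one row per condition.
#' @export
conditionTable <- function(x) {
  stopifnot(is(x, "TGPlate"))
  conds <- metadata(x)$conditions
  do.call(rbind, lapply(names(conds), function(ci) {
    cm <- conds[[ci]]
    data.frame(condition_id = ci, label = cm@label,
               fviii_level = cm@fviii_level, amc_spike = cm@amc_spike,
               substrate_total = cm@substrate_total,
               afc_substrate = cm@afc_substrate,
               calibrator_activity = cm@calibrator_activity,
               stringsAsFactors = FALSE)
  }))
}

#' @describeIn accessors status of an ActivityCurve, ThrombinCurve or
#'   TGParams object.
#' @export
curveStatus <- function(x) {
  stopifnot(is(x, "ActivityCurve") || is(x, "ThrombinCurve") ||
              is(x, "TGParams"))
  x@status
}

#' @describeIn accessors failure code string of any status-carrying object.
#' @export
statusCode <- function(x) {
  if (is(x, "FailureStatus")) x@code else curveStatus(x)@code
}

setMethod("show", "TGPlate", function(object) {
  cd <- colData(object)
  cat(sprintf("TGPlate: %d wells (%d sample, %d calibrator), %d timepoints\n",
              ncol(object), sum(cd$role == "sample"),
              sum(cd$role == "calibrator"), nrow(object)))
  tm <- plateTimes(object)
  cat(sprintf("  time: %.2f..%.2f min (step %.3g min)\n", tm[1],
              tm[length(tm)], stats::median(diff(tm))))
  cat(sprintf("  conditions: %d; scenario: %s\n",
              length(metadata(object)$conditions),
              if (is.null(metadata(object)$scenario)) "(none)"
              else metadata(object)$scenario))
})

setMethod("show", "TGWell", function(object) {
  cat(sprintf("TGWell '%s' (%s), %d points, %.1f min, condition %s\n",
              object@well_id, object@role, length(object@times),
              max(object@times), object@condition_id))
})

setMethod("show", "CalibModel", function(object) {
  cat(sprintf(
    "CalibModel: order %d, slope0 %.4g RFU/min, activity %g nM\n",
    object@order, object@slope0, object@activity))
  cat(sprintf("  F range [%.4g, %.4g] RFU, t range [%g, %g] min%s\n",
              object@f_range[1], object@f_range[2], object@t_range[1],
              object@t_range[2],
              if (object@monotone) "" else " [non-monotone fit]"))
})

setMethod("show", "ActivityCurve", function(object) {
  cat(sprintf("ActivityCurve (%s): %d points, status %s\n", object@method,
              length(object@times), object@status@code))
})

setMethod("show", "ThrombinCurve", function(object) {
  cat(sprintf("ThrombinCurve: %d points, k_a2m %.4g/min, status %s\n",
              length(object@times), object@k_a2m_used, object@status@code))
})

setMethod("show", "TGParams", function(object) {
  if (object@status@code == "no_curve") {
    cat("TGParams: no curve reported\n")
  } else {
    cat(sprintf(
      "TGParams: lag %.3g min, ttp %.3g min, TPH %.4g nM, ETP %.5g nM*min (%s)\n",
      object@lag_time, object@time_to_peak, object@tph, object@etp,
      object@status@code))
  }
})

setMethod("show", "FailureStatus", function(object) {
  cat(sprintf("FailureStatus: %s%s (noise amplification %.3g)\n",
              object@code,
              if (nzchar(object@detail)) paste0(" - ", object@detail) else "",
              object@noise_amplification))
})
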