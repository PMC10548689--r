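#' Define a severity grid for an edge-of-failure scan
#'
#' @param axis artifact axis: \code{"amc_spike"} (uM),
#'   \code{"substrate_total"} (uM, decreasing severity direction),
#'   \code{"tf_pM"} (pM) or \code{"at_fraction"} (fraction of normal,
#'   decreasing severity direction).
#' @param values ordered severity values, strictly monotone.
#' @param replicates simulated replicates per severity (>= 1).
#' @param seeds one integer seed per replicate.
#' @return list of class \code{"SeverityGrid"}.
#' @export
severityGrid <- function(axis = c("amc_spike", "substrate_total", "tf_pM",
                                  "at_fraction"),
                         values, replicates = 1L,
                         seeds = seq_len(replicates)) {
  axis <- match.arg(axis)
  if (length(values) < 1 ||
      !(all(diff(values) > 0) || all(diff(values) < 0)))
    stop("severity values must be strictly monotone")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1")
  if (length(seeds) != replicates)
    stop("need one seed per replicate")
  structure(list(axis = axis, values = values, replicates = replicates,
                 seeds = as.integer(seeds)), class = "SeverityGrid")
}

## build the one-condition scenario for a single severity cell
scenarioForSeverity <- function(axis, value, base) {
  sc <- if (is.null(base)) list() else base
  sc$scenario <- "custom"
  cond <- if (is.null(sc$condition)) list() else sc$condition
  kin <- if (is.null(sc$kinetics)) list() else sc$kinetics
  switch(axis,
    amc_spike = { cond$amc_spike <- value },
    substrate_total = { cond$substrate_total <- value },
    tf_pM = { kin$tf_pM <- value },
    at_fraction = { kin$at_fraction <- value })
  sc$conditions <- list(cond)
  sc$kinetics <- kin
  sc$condition <- NULL
  sc
}

#' Sweep artifact severity against correction methods
#'
#' For every (severity, replicate): simulate a one-condition plate with
#' its paired calibrator, run every requested method through the full
#' pipeline, and record parameters, failure status, and relative errors
#' against the simulator's ground truth. Deterministic given the grid's
#' seeds.
#'
#' @param grid a [severityGrid()].
#' @param methods character vector of preset names (see [methodPreset()]).
#' @param base_scenario optional list of scenario overrides shared by all
#'   cells (\code{condition}, \code{kinetics}, \code{optics}, ...).
#' @return list of class \code{"EdgeReport"}: \code{grid},
#'   \code{cells} (data.frame) and \code{set_points} (data.frame, one row
#'   per method, from [findSetPoint()]).
#' @examples
#' rep <- runScan(severityGrid("amc_spike", c(0, 100, 200)),
#'                methods = "cat_strict",
#'                base_scenario = list(optics = list(noise_sd = 0)))
#' rep$set_points
#' @export
runScan <- function(grid, methods = c("linear", "cat3sg", "cat4ss",
                                      "cat_strict"),
                    base_scenario = NULL) {
  stopifnot(inherits(grid, "SeverityGrid"))
  if (!length(methods)) stop("empty method list")
  cells <- list()
  for (iv in seq_along(grid$values)) {
    v <- grid$values[iv]
    sc <- scenarioForSeverity(grid$axis, v, base_scenario)
    for (ir in seq_len(grid$replicates)) {
      plate <- generatePlate(sc, seed = grid$seeds[ir])
      df <- analyzePlate(plate, methods = methods)
      df$severity <- v
      df$replicate <- ir
      cells[[length(cells) + 1L]] <- df
    }
  }
  cells <- do.call(rbind, cells)
  report <- structure(list(grid = grid, cells = cells,
                           set_points = NULL), class = "EdgeReport")
  report$set_points <- do.call(rbind, lapply(methods, function(m)
    findSetPoint(report, m)))
  report
}

#' Locate a method's edge-of-failure set point
#'
#' The smallest grid severity (in the grid's severity direction) at which
#' at least half of the replicates fail (status other than \code{ok});
#' \code{NA} when the method stays clean over the whole grid. The basis
#' records the dominant failure code at the set point.
#'
#' @param report an \code{EdgeReport} from [runScan()].
#' @param method preset name covered by the report.
#' @return one-row data.frame: method, axis, value, basis.
#' @export
findSetPoint <- function(report, method) {
  stopifnot(inherits(report, "EdgeReport"))
  cells <- report$cells[report$cells$method == method, ]
  if (!nrow(cells)) stop(sprintf("method '%s' absent from report", method))
  for (v in report$grid$values) {
    st <- cells$status[cells$severity == v]
    fail <- st != "ok"
    if (sum(fail) * 2 >= length(fail)) {
      codes <- table(st[fail])
      return(data.frame(method = method, axis = report$grid$axis,
                        value = v,
                        basis = names(codes)[which.max(codes)],
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(method = method, axis = report$grid$axis, value = NA_real_,
             basis = NA_character_, stringsAsFactors = FALSE)
}

#' Summarize an edge scan as a set-point table
#'
#' One row per (axis, method): the set point, a qualitative outcome label
#' — \code{"failed"} when any cell refused (\code{no_curve}),
#' \code{"overestimated"} when any reported TPH exceeds 1.1 x the ground
#' truth, \code{"corrected"} otherwise — and, for synthetic inputs, the
#' largest severity at which the TPH error stays below 10\%.
#'
#' @param report an \code{EdgeReport} from [runScan()].
#' @return A report document (list, class \code{"ReportDoc"}) with
#'   \code{cells} and \code{summary}; serializable via [writeReport()].
#' @export
summarizeTable <- function(report) {
  stopifnot(inherits(report, "EdgeReport"))
  cells <- report$cells
  methods <- unique(cells$method)
  summ <- do.call(rbind, lapply(methods, function(m) {
    cm <- cells[cells$method == m, ]
    sp <- findSetPoint(report, m)
    label <- if (any(cm$status == "no_curve")) "failed"
      else if (any(is.finite(cm$tph_rel_err) &
                   cm$tph > 1.1 * cm$tph_true)) "overestimated"
      else "corrected"
    # most severe = furthest along the grid's severity direction
    ok_sev <- cm$severity[is.finite(cm$tph_rel_err) & cm$tph_rel_err < 0.1]
    ok_sev <- ok_sev[order(match(ok_sev, report$grid$values))]
    data.frame(axis = report$grid$axis, method = m,
               set_point = sp$value, basis = sp$basis, outcome = label,
               max_severity_within_10pct =
                 if (length(ok_sev)) ok_sev[length(ok_sev)] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(cells = cells, summary = summ,
                 meta = list(axis = report$grid$axis,
                             values = report$grid$values,
                             replicates = report$grid$replicates)),
            class = "ReportDoc")
}
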