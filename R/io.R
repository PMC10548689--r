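#' @importFrom utils read.csv write.csv
NULL

fmtNum <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- ""
  out
}

serializeCondition <- function(cm) {
  paste(sprintf(
    "fviii_level=%s;amc_spike=%s;substrate_total=%s;afc_substrate=%s;kcat=%s;Km=%s;calibrator_activity=%s;sampling_interval=%s;duration=%s;label=%s",
    fmtNum(cm@fviii_level), fmtNum(cm@amc_spike),
    fmtNum(cm@substrate_total), fmtNum(cm@afc_substrate), fmtNum(cm@kcat),
    fmtNum(cm@Km), fmtNum(cm@calibrator_activity),
    fmtNum(cm@sampling_interval), fmtNum(cm@duration), cm@label))
}

parseCondition <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=")
  args <- list()
  for (p in kv) {
    key <- p[1]
    val <- paste(p[-1], collapse = "=")
    args[[key]] <- if (key == "label") val else as.numeric(val)
  }
  do.call(conditionMeta, args)
}

#' Write a plate to CSV
#'
#' Self-contained plate file: a commented header block (\code{# key: value})
#' carrying scenario, conditions, well roles and the sample-to-calibrator
#' pairing, followed by the time series in the requested dialect —
#' \code{long} (\code{time_min, well, rfu}) or \code{wide}
#' (\code{time_min} plus one column per well). Deterministic column order
#' and 9-significant-digit formatting make repeated writes byte-identical.
#'
#' @param plate a [TGPlate-class].
#' @param path output file path.
#' @param dialect \code{"long"} or \code{"wide"}.
#' @return \code{path}, invisibly.
#' @export
writePlate <- function(plate, path, dialect = c("long", "wide")) {
  stopifnot(is(plate, "TGPlate"))
  dialect <- match.arg(dialect)
  if (ncol(plate) == 0) stop("plate has no wells; nothing to write")
  cd <- colData(plate)
  md <- metadata(plate)
  hdr <- c("# tgedge-plate v1",
           sprintf("# dialect: %s", dialect))
  if (!is.null(md$scenario))
    hdr <- c(hdr, sprintf("# scenario: %s", md$scenario))
  if (!is.null(md$seed))
    hdr <- c(hdr, sprintf("# seed: %d", as.integer(md$seed)))
  for (ci in names(md$conditions))
    hdr <- c(hdr, sprintf("# condition %s: %s", ci,
                          serializeCondition(md$conditions[[ci]])))
  for (i in seq_len(nrow(cd)))
    hdr <- c(hdr, sprintf("# well %s: role=%s;condition=%s",
                          cd$well_id[i], cd$role[i], cd$condition_id[i]))
  for (ci in names(md$pairing))
    hdr <- c(hdr, sprintf("# pairing %s: %s", ci,
                          paste(md$pairing[[ci]], collapse = ",")))
  tm <- plateTimes(plate)
  m <- assay(plate, "rfu")
  con <- file(path, "wb")          # binary mode: stable newlines
  on.exit(close(con))
  writeLines(hdr, con)
  if (dialect == "long") {
    writeLines("time_min,well,rfu", con)
    for (i in seq_len(ncol(m)))
      writeLines(sprintf("%s,%s,%s", fmtNum(tm), cd$well_id[i],
                         fmtNum(m[, i])), con)
  } else {
    writeLines(paste(c("time_min", cd$well_id), collapse = ","), con)
    body <- cbind(fmtNum(tm),
                  matrix(fmtNum(m), nrow = nrow(m)))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a plate from CSV
#'
#' Counterpart of [writePlate()]: parses the commented metadata header and
#' the long or wide body. A \code{time_s} column is converted to minutes.
#' Validation is strict: duplicated well ids, non-monotone times (the
#' error names the well), ragged series, and sample conditions without a
#' paired calibrator are all hard errors.
#'
#' @param path file path.
#' @param dialect \code{"auto"} (from the header), \code{"long"} or
#'   \code{"wide"}.
#' @return A [TGPlate-class].
#' @export
readPlate <- function(path, dialect = c("auto", "long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]

  grab <- function(pattern) {
    hit <- grep(pattern, hdr, value = TRUE)
    sub(pattern, "\\1", hit)
  }
  if (dialect == "auto") {
    d <- grab("^# dialect: (.*)$")
    dialect <- if (length(d)) d[1]
      else if (grepl("^time_(min|s),well,rfu", body[1])) "long" else "wide"
  }
  conditions <- list()
  for (h in grep("^# condition ", hdr, value = TRUE)) {
    ci <- sub("^# condition ([^:]+): .*$", "\\1", h)
    conditions[[ci]] <- parseCondition(sub("^# condition [^:]+: ", "", h))
  }
  roles <- list()
  for (h in grep("^# well ", hdr, value = TRUE)) {
    wid <- sub("^# well ([^:]+): .*$", "\\1", h)
    if (!is.null(roles[[wid]]))
      stop(sprintf("duplicated well_id '%s' in metadata block", wid))
    kv <- strsplit(sub("^# well [^:]+: ", "", h), ";")[[1]]
    roles[[wid]] <- list(
      role = sub("^role=", "", kv[grepl("^role=", kv)]),
      condition = sub("^condition=", "", kv[grepl("^condition=", kv)]))
  }
  if (!length(roles))
    stop("plate file lacks the well metadata block (roles/conditions)")
  pairing <- list()
  for (h in grep("^# pairing ", hdr, value = TRUE)) {
    ci <- sub("^# pairing ([^:]+): .*$", "\\1", h)
    pairing[[ci]] <- strsplit(sub("^# pairing [^:]+: ", "", h), ",")[[1]]
  }
  sc <- grab("^# scenario: (.*)$")
  seed <- grab("^# seed: (.*)$")

  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  tcol <- intersect(c("time_min", "time_s"), names(df))
  if (!length(tcol)) stop("no time_min or time_s column")
  tdiv <- if (tcol[1] == "time_s") 60 else 1
  if (dialect == "long") {
    if (!all(c("well", "rfu") %in% names(df)))
      stop("long dialect needs columns time, well, rfu")
    split_w <- split(df, df$well)
    ids <- names(split_w)
    lens <- vapply(split_w, nrow, integer(1))
    if (length(unique(lens)) != 1)
      stop(sprintf("ragged series: wells %s differ in length",
                   paste(ids[lens != stats::median(lens)], collapse = ", ")))
    times <- NULL
    wells <- lapply(ids, function(wid) {
      sub <- split_w[[wid]]
      tt <- sub[[tcol[1]]] / tdiv
      if (any(diff(tt) <= 0))
        stop(sprintf("non-monotone time in well '%s'", wid))
      times <<- tt
      meta <- roles[[wid]]
      if (is.null(meta))
        stop(sprintf("well '%s' missing from the metadata block", wid))
      cm <- conditions[[meta$condition]]
      if (is.null(cm)) cm <- conditionMeta()
      new("TGWell", well_id = wid, role = meta$role,
          condition_id = meta$condition, condition = cm,
          times = tt, rfu = sub$rfu)
    })
  } else {
    raw_names <- strsplit(body[1], ",", fixed = TRUE)[[1]]
    if (anyDuplicated(raw_names))
      stop(sprintf("duplicated well_id '%s' in wide header",
                   raw_names[duplicated(raw_names)][1]))
    ids <- setdiff(names(df), tcol)
    tt <- df[[tcol[1]]] / tdiv
    if (any(diff(tt) <= 0)) stop("non-monotone time column")
    wells <- lapply(ids, function(wid) {
      meta <- roles[[wid]]
      if (is.null(meta))
        stop(sprintf("well '%s' missing from the metadata block", wid))
      cm <- conditions[[meta$condition]]
      if (is.null(cm)) cm <- conditionMeta()
      new("TGWell", well_id = wid, role = meta$role,
          condition_id = meta$condition, condition = cm,
          times = tt, rfu = df[[wid]])
    })
  }
  newTGPlate(wells, conditions, pairing,
             scenario = if (length(sc)) sc[1] else NULL,
             seed = if (length(seed)) as.integer(seed[1]) else NULL)
}

#' Export retained ground truth as a companion CSV
#'
#' @param plate a simulated [TGPlate-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(plate, path) {
  stopifnot(is(plate, "TGPlate"))
  gts <- metadata(plate)$ground_truth
  if (is.null(gts)) stop("plate carries no ground truth")
  rows <- lapply(names(gts), function(wid) {
    g <- gts[[wid]]
    data.frame(well = wid, time_min = g@times,
               free_thrombin = g@free_thrombin,
               a2m_thrombin = g@a2m_thrombin, amidolytic = g@amidolytic,
               substrate = if (length(g@substrate)) g@substrate else NA,
               product = if (length(g@product)) g@product else NA)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' JSON is a lossless serialization of the report tree; CSV flattens to
#' one row per (condition, method) cell, with empty parameter fields and
#' status \code{"failed"} for cells where no curve was reported.
#'
#' @param report a \code{ReportDoc} (from [summarizeTable()]) or any list
#'   with a \code{cells} data.frame.
#' @param path output path.
#' @param format \code{"json"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  cells <- if (is.data.frame(report)) report else report$cells
  if (is.null(cells)) stop("report carries no cells")
  # the cell unit: (severity, replicate) for scans, otherwise the well
  keys <- if ("severity" %in% names(cells))
    intersect(c("severity", "replicate"), names(cells))
  else intersect(c("well_id", "condition_id"), names(cells))[1]
  keys <- keys[!is.na(keys)]
  if (length(keys) && "method" %in% names(cells)) {
    grid_keys <- c(keys, "method")
    combo <- do.call(paste, c(cells[grid_keys], sep = "|"))
    expected <- do.call(paste, c(expand.grid(
      lapply(cells[grid_keys], unique), stringsAsFactors = FALSE),
      sep = "|"))
    missing <- setdiff(expected, combo)
    if (length(missing))
      stop(sprintf("incomplete report grid; missing pairs: %s",
                   paste(utils::head(missing, 10), collapse = "; ")))
  }
  if (format == "json") {
    obj <- if (is.data.frame(report)) list(cells = report)
           else unclass(report)
    obj$grid <- NULL    # SeverityGrid object does not serialize usefully
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    out <- cells
    failed <- out$status == "no_curve"
    out$status[failed] <- "failed"
    for (cn in c("lag_time", "time_to_peak", "tph", "etp"))
      if (cn %in% names(out)) {
        out[[cn]] <- fmtNum(out[[cn]])
        out[[cn]][failed] <- ""
      }
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a scenario or scan configuration
#'
#' YAML (or JSON) key tree with blocks \code{scenario}, \code{kinetics},
#' \code{optics}, \code{conditions}/scenario options, \code{replicates},
#' \code{seed}. Validated against the known scenario names and parameter
#' fields by [generatePlate()].
#'
#' @param path config file path.
#' @return named list usable as \code{generatePlate(scenario = ...)}.
#' @export
readScenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario))
    stop("config must name a scenario")
  cfg
}
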