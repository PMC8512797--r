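#' @include study-pipeline.R
NULL

## On-disk formats
## ---------------
## A recording is a channel-matrix CSV (rows = samples, one column per valid
## channel, header "r<row>c<col>" with 0-based grid indices, canonical
## column-major channel order) plus a JSON sidecar <stem>.json describing
## the sampling rate, grid geometry (rows, cols, missing electrodes,
## channel-order convention, row 0 = top of grid as placed), trial metadata
## and processing provenance. A force trace is a two-column CSV
## (time_s, force_n) plus sidecar. Values are written with 17 significant
## digits so round trips are lossless at double precision.

.sidecarPath <- function(path) paste0(sub("\\.csv$", "", path), ".json")

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  dim(out) <- dim(x)
  out
}

.layoutToJSON <- function(layout) {
  list(n_rows = layout@nRows, n_cols = layout@nCols,
       missing = if (nrow(layout@missing)) unname(apply(layout@missing, 1,
                                                        as.list))
                 else list(),
       channel_order = "column-major, row 0 = top of grid as placed",
       inter_electrode_distance_mm = layout@interElectrodeDistance)
}

.layoutFromJSON <- function(g) {
  miss <- if (length(g$missing))
    do.call(rbind, lapply(g$missing, function(p) as.integer(unlist(p))))
  else matrix(integer(), 0, 2)
  gridLayout(nRows = g$n_rows, nCols = g$n_cols, missing = miss,
             interElectrodeDistance = g$inter_electrode_distance_mm)
}

#' Write / read a grid recording (channel-matrix CSV + JSON sidecar)
#'
#' @param recording an [EMGRecording-class].
#' @param path CSV path; the sidecar is written alongside as
#'   \code{<stem>.json}.
#' @return \code{writeRecording}: the path, invisibly. \code{readRecording}:
#'   the [EMGRecording-class]; the CSV header is validated against the
#'   sidecar's electrode mask and mismatches are parse errors naming the
#'   offending channel.
#' @export
writeRecording <- function(recording, path) {
  x <- samples(recording)
  txt <- .fmtNum(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = ","), con)
  writeLines(apply(txt, 1, paste, collapse = ","), con)
  side <- list(format = "gridEMG-recording/1",
               sampling_rate_hz = samplingRate(recording),
               grid = .layoutToJSON(gridLayoutOf(recording)),
               meta = metaData(recording))
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  scPath <- .sidecarPath(path)
  if (!file.exists(scPath))
    .gridEMGStop("gridEMG_parse_error",
                 sprintf("missing sidecar %s", scPath))
  side <- jsonlite::read_json(scPath)
  layout <- .layoutFromJSON(side$grid)
  want <- channelNames(layout)
  x <- tryCatch(
    as.matrix(utils::read.csv(path, colClasses = "numeric",
                              check.names = FALSE)),
    error = function(e) .gridEMGStop("gridEMG_parse_error", sprintf(
      "%s: cannot parse channel matrix (%s)", path, conditionMessage(e))),
    warning = function(e) .gridEMGStop("gridEMG_parse_error", sprintf(
      "%s: cannot parse channel matrix (%s)", path, conditionMessage(e))))
  if (!identical(colnames(x), want)) {
    missing <- setdiff(want, colnames(x))
    extra <- setdiff(colnames(x), want)
    .gridEMGStop("gridEMG_parse_error", sprintf(
      "%s: header does not match sidecar mask (missing: %s; unexpected: %s)",
      path,
      if (length(missing)) paste(missing, collapse = " ") else "none",
      if (length(extra)) paste(extra, collapse = " ") else "none"))
  }
  if (anyNA(x))
    .gridEMGStop("gridEMG_parse_error",
                 sprintf("%s: non-numeric or empty cells", path))
  meta <- side$meta
  emgRecording(x, samplingRate = side$sampling_rate_hz, layout = layout,
               meta = if (is.null(meta)) list() else meta)
}

#' Write / read a force trace (two-column CSV + JSON sidecar)
#'
#' @param force a [ForceTrace-class].
#' @param path CSV path (columns \code{time_s}, \code{force_n}); sidecar
#'   written alongside.
#' @return \code{writeForce}: the path, invisibly. \code{readForce}: the
#'   [ForceTrace-class]. A non-monotone time column is an error; a
#'   single-column file is accepted when the sidecar carries the rate.
#' @export
writeForce <- function(force, path) {
  f <- forceValues(force)
  t <- (seq_along(f) - 1) / samplingRate(force)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("time_s,force_n", con)
  writeLines(paste(sprintf("%.17g", t), sprintf("%.17g", f), sep = ","), con)
  jsonlite::write_json(
    list(format = "gridEMG-force/1",
         sampling_rate_hz = samplingRate(force)),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeForce
#' @export
readForce <- function(path) {
  d <- tryCatch(
    utils::read.csv(path, colClasses = "numeric", check.names = FALSE),
    error = function(e) .gridEMGStop("gridEMG_parse_error", sprintf(
      "%s: cannot parse force file (%s)", path, conditionMessage(e))))
  scPath <- .sidecarPath(path)
  rate <- NULL
  if (file.exists(scPath))
    rate <- jsonlite::read_json(scPath)$sampling_rate_hz
  if ("time_s" %in% names(d)) {
    dt <- diff(d$time_s)
    if (any(dt <= 0))
      .gridEMGStop("gridEMG_parse_error", sprintf(
        "%s: time column is not strictly increasing (first violation at row %d)",
        path, which(dt <= 0)[1] + 1L))
    if (is.null(rate)) rate <- 1 / stats::median(dt)
  } else if (is.null(rate)) {
    .gridEMGStop("gridEMG_parse_error", sprintf(
      "%s: no time column and no sampling rate in sidecar", path))
  }
  forceTrace(d$force_n, samplingRate = rate)
}

#' Write a simulated study to a directory
#'
#' Serializes every trial bundle of an [EMGStudy-class] in the package's
#' on-disk formats: per-side push-recording CSVs, the force CSV, and each
#' participant/muscle/side MVC trial set (written once), all with JSON
#' sidecars. The result is indistinguishable from an imported study and can
#' be read back with [readStudy()].
#'
#' @param study an [EMGStudy-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (b in study@bundles) {
    m <- b$meta
    stem <- sprintf("%s_%s_%s", m$participant, m$muscle, m$design)
    for (s in names(b$recordings))
      writeRecording(b$recordings[[s]],
                     file.path(dir, sprintf("%s_%s_emg.csv", stem, s)))
    writeForce(b$force, file.path(dir, sprintf("%s_force.csv", stem)))
    for (s in names(b$mvc)) {
      key <- sprintf("%s_%s_%s", m$participant, m$muscle, s)
      if (key %in% written) next
      written <- c(written, key)
      for (i in seq_along(b$mvc[[s]]))
        writeRecording(b$mvc[[s]][[i]],
                       file.path(dir, sprintf("%s_mvc%d.csv", key, i)))
    }
  }
  invisible(dir)
}

#' Read a study directory into trial bundles
#'
#' Scans a directory written by [writeStudy()] (or assembled by hand in the
#' same formats), groups files into trial bundles by sidecar metadata, and
#' attaches each participant/muscle/side MVC trial set to the bundles that
#' use it.
#'
#' @param dir the study directory.
#' @return list of trial bundles as in [generateStudy()].
#' @export
readStudy <- function(dir) {
  files <- list.files(dir, pattern = "_emg\\.csv$", full.names = TRUE)
  mvcFiles <- list.files(dir, pattern = "_mvc[0-9]+\\.csv$",
                         full.names = TRUE)
  if (length(files) == 0L)
    .gridEMGStop("gridEMG_no_trials", sprintf("no trials found in %s", dir))
  recs <- lapply(sort(files), readRecording)
  mvcRecs <- lapply(sort(mvcFiles), readRecording)
  mvcKey <- vapply(mvcRecs, function(r) {
    m <- metaData(r)
    paste(m$participant, m$muscle, m$side)
  }, character(1))
  key <- vapply(recs, function(r) {
    m <- metaData(r)
    paste(m$participant, m$muscle, m$design)
  }, character(1))
  bundles <- lapply(split(recs, key), function(group) {
    m <- metaData(group[[1]])
    stem <- sprintf("%s_%s_%s", m$participant, m$muscle, m$design)
    sides <- vapply(group, function(r) metaData(r)$side, character(1))
    recordings <- stats::setNames(group, sides)
    mvc <- stats::setNames(lapply(sides, function(s)
      mvcRecs[mvcKey == paste(m$participant, m$muscle, s)]), sides)
    mvc <- Filter(length, mvc)
    list(recordings = recordings,
         force = readForce(file.path(dir, sprintf("%s_force.csv", stem))),
         mvc = if (length(mvc)) mvc else NULL,
         meta = list(participant = m$participant, sex = m$sex,
                     muscle = m$muscle, design = m$design))
  })
  unname(bundles)
}

#' Write / read a tidy feature table
#'
#' One row per processed trial record, schema as [processTrial()].
#'
#' @param records data.frame of trial records.
#' @param path CSV path.
#' @return \code{writeFeatures}: the path invisibly; \code{readFeatures}:
#'   the data.frame.
#' @export
writeFeatures <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant = "character"))
}
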