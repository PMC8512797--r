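#' @include spatial-maps.R
NULL

.featureCols <- c("intensity", "differential_intensity", "mean_rms_pct",
                  "entropy_bits", "cov_pct")

#' Process one push trial into a tidy record
#'
#' Runs the full per-trial pipeline: band-pass filter, force-triggered
#' initiation-window detection, RMS activation map, MVC normalization, and
#' the five spatial features. Any stage failure is caught and returned as a
#' failed record carrying the trial identity and the error message — trials
#' are never dropped silently, so group Ns remain auditable.
#'
#' @param recording a raw [EMGRecording-class] push trial.
#' @param force the paired [ForceTrace-class].
#' @param mvc an [MVCReference-class], or a list of MVC
#'   [EMGRecording-class] trials (reduced via [computeMVC()]), or
#'   \code{NULL} (mean RMS then \code{NA}).
#' @param options named list of pipeline settings: \code{low}, \code{high}
#'   (band edges, Hz), \code{thresholdN}, \code{windowS}, \code{offsetS},
#'   \code{minHoldS}, \code{diAggregate}, \code{covSdType},
#'   \code{mvcWindowS}.
#' @return a one-row data.frame with columns \code{participant}, \code{sex},
#'   \code{muscle}, \code{side}, \code{design}, the five features
#'   (\code{intensity}, \code{differential_intensity}, \code{mean_rms_pct},
#'   \code{entropy_bits}, \code{cov_pct}), \code{n_channels},
#'   \code{qc_flags}, \code{status} (\code{"ok"}/\code{"failed"}) and
#'   \code{error}.
#' @export
processTrial <- function(recording, force, mvc = NULL, options = list()) {
  o <- utils::modifyList(
    list(low = 10, high = 500, thresholdN = 20, windowS = 0.5, offsetS = 0,
         minHoldS = 0, diAggregate = "log-of-mean", covSdType = "sample",
         mvcWindowS = 0.5),
    options)
  meta <- metaData(recording)
  id <- data.frame(
    participant = .metaChr(meta, "participant"),
    sex = .metaChr(meta, "sex"),
    muscle = .metaChr(meta, "muscle"),
    side = .metaChr(meta, "side"),
    design = .metaChr(meta, "design"),
    stringsAsFactors = FALSE)
  res <- tryCatch({
    filt <- bandpassRecording(recording, low = o$low, high = o$high)
    win <- detectInitiation(force, thresholdN = o$thresholdN,
                            windowS = o$windowS, offsetS = o$offsetS,
                            minHoldS = o$minHoldS)
    ref <- mvc
    if (is.list(mvc) && !is(mvc, "MVCReference"))
      ref <- computeMVC(mvc, windowS = o$mvcWindowS)
    feats <- spatialFeatures(filt, win, mvc = ref,
                             diAggregate = o$diAggregate,
                             covSdType = o$covSdType)
    cbind(id, as.data.frame(feats),
          data.frame(status = "ok", error = NA_character_,
                     stringsAsFactors = FALSE))
  }, gridEMGError = function(e) {
    cbind(id,
          data.frame(intensity = NA_real_, differential_intensity = NA_real_,
                     mean_rms_pct = NA_real_, entropy_bits = NA_real_,
                     cov_pct = NA_real_, n_channels = NA_integer_,
                     qc_flags = "", status = "failed",
                     error = conditionMessage(e), stringsAsFactors = FALSE))
  })
  rownames(res) <- NULL
  res
}

.metaChr <- function(meta, key) {
  v <- meta[[key]]
  if (is.null(v)) NA_character_ else as.character(v)
}

#' Enumerate the expected trials of a study design
#'
#' A participant completes one recording trial per combination of the six
#' handle designs and the three bilateral muscle pairs: 18 trials. This
#' enumerates them (and, with \code{records}, checks completeness of a
#' delivered feature table against the expectation).
#'
#' @param design a [StudyDesign-class].
#' @param records optional processed-record data.frame to check against.
#' @param designs optional subset of handle designs to restrict the
#'   enumeration to (e.g. \code{"HH"} gives 3 trials per participant).
#' @return data.frame with columns \code{participant}, \code{design},
#'   \code{muscle}, one row per expected trial
#'   (\code{nParticipants * 18} rows); when \code{records} is given, an
#'   extra logical column \code{delivered}.
#' @examples
#' nrow(enumerateTrials(studyDesign(nParticipants = 1)))   # 18
#' nrow(enumerateTrials(studyDesign(nParticipants = 20)))  # 360
#' @export
enumerateTrials <- function(design, records = NULL, designs = design@designs) {
  validObject(design)
  stopifnot(all(designs %in% design@designs))
  out <- expand.grid(
    muscle = design@muscles, design = designs,
    participant = sprintf("P%02d", seq_len(design@nParticipants)),
    stringsAsFactors = FALSE)
  out <- out[, c("participant", "design", "muscle")]
  rownames(out) <- NULL
  if (!is.null(records)) {
    key <- paste(out$participant, out$design, out$muscle)
    got <- paste(records$participant, records$design, records$muscle)
    out$delivered <- key %in% got
  }
  out
}

#' Process every trial of a (simulated or imported) study
#'
#' Applies [processTrial()] to both sides of every trial bundle, computing
#' each participant/muscle/side MVC reference once.
#'
#' @param study an [EMGStudy-class] from [generateStudy()] (or an equivalent
#'   bundle list).
#' @param options pipeline options passed to [processTrial()].
#' @return data.frame of per-side trial records
#'   (2 rows per bundle), schema as [processTrial()].
#' @export
processStudy <- function(study, options = list()) {
  bundles <- if (is(study, "EMGStudy")) study@bundles else study
  mvcCache <- new.env(parent = emptyenv())
  rows <- vector("list", 2L * length(bundles))
  k <- 0L
  mvcWindowS <- if (is.null(options$mvcWindowS)) 0.5 else options$mvcWindowS
  for (b in bundles) {
    for (s in names(b$recordings)) {
      rec <- b$recordings[[s]]
      mvcRef <- NULL
      if (!is.null(b$mvc[[s]])) {
        key <- paste(b$meta$participant, b$meta$muscle, s)
        if (!is.null(mvcCache[[key]])) mvcRef <- mvcCache[[key]]
        else {
          mvcRef <- computeMVC(b$mvc[[s]], windowS = mvcWindowS)
          mvcCache[[key]] <- mvcRef
        }
      }
      k <- k + 1L
      rows[[k]] <- processTrial(rec, b$force, mvcRef, options)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Summarize a study feature table by group
#'
#' Group mean and SD of every feature, per handle design (default) or any
#' grouping of \code{design}, \code{muscle}, \code{side}, \code{sex},
#' \code{participant}. Failed trials are excluded from the statistics but
#' counted, so group Ns stay auditable; single-record groups get
#' \code{sd_defined = FALSE} rather than being dropped. The resulting tidy
#' table is the substrate for external inferential statistics.
#'
#' @param records data.frame from [processStudy()]/[processTrial()].
#' @param by character vector of grouping columns (default \code{"design"}).
#' @return data.frame: grouping columns, \code{n} (successful records),
#'   \code{n_failed}, \code{<feature>_mean} and \code{<feature>_sd} for each
#'   feature, and \code{sd_defined}.
#' @export
summarizeStudy <- function(records, by = "design") {
  if (is.null(records) || nrow(records) == 0L)
    .configError("no records to summarize")
  stopifnot(all(by %in% names(records)))
  keys <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  parts <- split(records, keys)
  out <- lapply(parts, function(g) {
    ok <- g[g$status == "ok", , drop = FALSE]
    row <- g[1, by, drop = FALSE]
    row$n <- nrow(ok)
    row$n_failed <- nrow(g) - nrow(ok)
    for (f in .featureCols) {
      row[[paste0(f, "_mean")]] <- if (nrow(ok)) mean(ok[[f]]) else NA_real_
      row[[paste0(f, "_sd")]] <- if (nrow(ok) > 1) stats::sd(ok[[f]])
                                 else NA_real_
    }
    row$sd_defined <- nrow(ok) > 1L
    row
  })
  res <- do.call(rbind, out)
  res <- res[do.call(order, res[by]), , drop = FALSE]
  rownames(res) <- NULL
  res
}
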