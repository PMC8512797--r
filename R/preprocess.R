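#' @include filter.R
NULL

#' Detect the push-initiation window from a force trace
#'
#' Finds the first sample at which the hand force strictly exceeds the
#' threshold (default 20 N) and returns the analysis window of the given
#' length (default 0.5 s) starting at that sample: the initiation period of
#' the push. An optional offset shifts the window start relative to the
#' crossing (for the alternative reading in which the window begins 0.5 s
#' after the crossing, pass \code{offsetS = 0.5}). An optional minimum-hold
#' duration requires the force to stay above threshold for that long,
#' guarding against noise spikes in imported data.
#'
#' @param force a [ForceTrace-class].
#' @param thresholdN force threshold in newtons (default 20).
#' @param windowS window length in seconds (default 0.5).
#' @param offsetS window start offset after the crossing, seconds (default 0).
#' @param minHoldS minimum time the force must remain above threshold for a
#'   crossing to count, seconds (default 0 = first strictly-greater sample).
#' @return a [TrialWindow-class] \code{[t0, t0 + windowS)}.
#' @section Errors:
#' \describe{
#'   \item{\code{gridEMG_no_initiation}}{the force never exceeds the
#'     threshold (for the required hold time).}
#'   \item{\code{gridEMG_truncated_window}}{the crossing lies too close to
#'     the end of the trace to fit the window.}
#' }
#' @examples
#' f <- forceTrace(c(rep(0, 1000), rep(30, 1000)))
#' detectInitiation(f)  # window [1001, 1501)
#' @export
detectInitiation <- function(force, thresholdN = 20, windowS = 0.5,
                             offsetS = 0, minHoldS = 0) {
  fs <- samplingRate(force)
  f <- forceValues(force)
  above <- f > thresholdN
  hold <- max(1L, round(minHoldS * fs))
  if (hold > 1L) {
    ## first index starting a run of >= hold samples above threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= hold)
    idx <- if (length(ok)) ends[ok[1]] - r$lengths[ok[1]] + 1L else NA_integer_
  } else {
    idx <- if (any(above)) which(above)[1] else NA_integer_
  }
  if (is.na(idx))
    .gridEMGStop("gridEMG_no_initiation", sprintf(
      "no initiation detected: force never exceeds %g N", thresholdN))
  start <- idx + round(offsetS * fs)
  len <- round(windowS * fs)
  if (start + len - 1L > length(f))
    .gridEMGStop("gridEMG_truncated_window", sprintf(
      "truncated window: crossing at sample %d leaves less than %g s of trace",
      idx, windowS + offsetS))
  trialWindow(start, start + len, samplingRate = fs)
}

## Per-channel maximum of sliding-window RMS, window length w samples.
## cumsum-based so MVC reduction over 5 s trials stays cheap.
.slidingMaxRMS <- function(x, w) {
  n <- nrow(x)
  if (w > n) w <- n
  cs <- apply(x^2, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  sums <- cs[w:n, , drop = FALSE] -
    rbind(0, cs[seq_len(n - w), , drop = FALSE])
  sqrt(apply(sums, 2, max) / w)
}

#' Compute an MVC normalization reference
#'
#' For each valid electrode, takes the maximum across the calibration trials
#' of the RMS over a sliding window (default 0.5 s, matching the analysis
#' window) — the standard amplitude-reference reduction for maximal
#' voluntary contractions.
#'
#' @param trials list of [EMGRecording-class] MVC trials (typically three
#'   five-second maximal contractions) with matching layouts.
#' @param windowS sliding-window length in seconds (default 0.5).
#' @return an [MVCReference-class] with strictly positive per-channel values.
#' @section Errors:
#' \code{gridEMG_degenerate_mvc} if any channel is identically zero across
#' all trials (its \%MVC would be undefined).
#' @export
computeMVC <- function(trials, windowS = 0.5) {
  if (length(trials) < 1L) .configError("need at least one MVC trial")
  lay <- gridLayoutOf(trials[[1]])
  nm <- channelNames(lay)
  for (tr in trials)
    if (!identical(channelNames(tr), nm))
      .configError("MVC trials have mismatched layouts")
  w <- round(windowS * samplingRate(trials[[1]]))
  perTrial <- vapply(trials, function(tr) .slidingMaxRMS(samples(tr), w),
                     numeric(length(nm)))
  ref <- apply(matrix(perTrial, nrow = length(nm)), 1, max)
  if (any(ref <= 0))
    .gridEMGStop("gridEMG_degenerate_mvc", sprintf(
      "degenerate MVC: channel(s) %s identically zero in every trial",
      paste(nm[ref <= 0], collapse = ", ")))
  vc <- validChannels(lay)
  vals <- matrix(NA_real_, lay@nRows, lay@nCols)
  vals[cbind(vc$row + 1L, vc$col + 1L)] <- ref
  meta <- metaData(trials[[1]])
  new("MVCReference", values = vals, layout = lay,
      muscle = if (is.null(meta$muscle)) NA_character_ else meta$muscle,
      side = if (is.null(meta$side)) NA_character_ else meta$side)
}

#' Normalize an activation map to an MVC reference
#'
#' Divides each valid channel of a raw activation map by its per-channel MVC
#' reference, expressing the map as fractions of the individual's maximal
#' voluntary contraction (multiply by 100 for \%MVC). Normalizing an already
#' normalized map, or mixing layouts, is an error.
#'
#' @param map a raw [ActivationMap-class].
#' @param mvc an [MVCReference-class] on the same layout.
#' @return the normalized [ActivationMap-class].
#' @export
normalizeMap <- function(map, mvc) {
  if (isNormalized(map))
    .configError("map is already normalized to MVC")
  lm <- gridLayoutOf(map); lr <- gridLayoutOf(mvc)
  if (!identical(lm@nRows, lr@nRows) || !identical(lm@nCols, lr@nCols) ||
      !identical(lm@missing, lr@missing))
    .configError("map and MVC reference layouts do not match")
  new("ActivationMap", values = mapValues(map) / mapValues(mvc),
      layout = lm, normalized = TRUE, window = map@window)
}
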