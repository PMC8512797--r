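#' @include preprocess.R
NULL

.rms <- function(x) sqrt(mean(x^2))

.validValues <- function(map) {
  v <- mapValues(map)
  v[!is.na(v)]
}

#' Build an RMS activation map from a trial window
#'
#' Computes \eqn{HM_{i,j} = RMS(sEMG_{i,j})} over the half-open sample
#' window for every valid electrode, yielding the 2-D heat-intensity map of
#' the trial.
#'
#' @param recording an [EMGRecording-class] (typically band-pass filtered).
#' @param window a [TrialWindow-class] inside the recording; \code{NULL}
#'   uses the whole recording.
#' @return a raw [ActivationMap-class] carrying the window as provenance.
#' @examples
#' rec <- generateGridEMG(simConfig(duration = 1))
#' m <- buildActivationMap(rec)
#' @export
buildActivationMap <- function(recording, window = NULL) {
  x <- samples(recording)
  if (is.null(window))
    window <- trialWindow(1L, nrow(x) + 1L, samplingRate(recording))
  if (window@endIndex - 1L > nrow(x) || window@startIndex < 1L)
    .configError(sprintf(
      "window [%d, %d) outside recording of %d samples",
      window@startIndex, window@endIndex, nrow(x)))
  seg <- x[window@startIndex:(window@endIndex - 1L), , drop = FALSE]
  if (nrow(seg) == 0L) .configError("empty analysis window")
  rms <- sqrt(colMeans(seg^2))
  lay <- gridLayoutOf(recording)
  vc <- validChannels(lay)
  vals <- matrix(NA_real_, lay@nRows, lay@nCols)
  vals[cbind(vc$row + 1L, vc$col + 1L)] <- rms
  new("ActivationMap", values = vals, layout = lay, normalized = FALSE,
      window = window)
}

#' @rdname mapIntensity
#' @export
setMethod("mapIntensity", "ActivationMap", function(x) {
  v <- .validValues(x)
  if (length(v) < 1L) .configError("map has no valid channel")
  m <- mean(v)
  if (m <= 0)
    .gridEMGStop("gridEMG_undefined_intensity",
                 "undefined intensity: map mean is zero")
  log10(m)
})

#' Differential intensity along the fiber direction
#'
#' Forms the single-differential signal of every pair of adjacent valid
#' electrodes within each grid column (the fiber direction), computes each
#' pair's RMS over the analysis window, and returns the common logarithm of
#' the mean pair RMS: \eqn{DI = \log_{10}(\overline{RMS(sEMG_{i,j} -
#' sEMG_{i+1,j})})}. On the full default grid there are up to 7 pairs per
#' column x 4 columns = 28 differential channels, fewer where the missing
#' electrode breaks a pair. Because differentials cancel common-mode
#' activity, a recording whose channels are identical yields all-zero
#' differentials; the value is then floored at \code{log10(.Machine$double.eps)}
#' and flagged.
#'
#' @param recording an [EMGRecording-class].
#' @param window a [TrialWindow-class]; \code{NULL} = whole recording.
#' @param aggregate \code{"log-of-mean"} (default: log10 of the mean pair
#'   RMS, mirroring the intensity feature) or \code{"mean-of-logs"} (mean of
#'   per-pair log10 RMS).
#' @return numeric DI in log10 a.u., with attributes \code{nPairs} and
#'   \code{floored} (logical).
#' @export
differentialIntensity <- function(recording, window = NULL,
                                  aggregate = c("log-of-mean",
                                                "mean-of-logs")) {
  aggregate <- match.arg(aggregate)
  x <- samples(recording)
  if (is.null(window))
    window <- trialWindow(1L, nrow(x) + 1L, samplingRate(recording))
  if (window@endIndex - 1L > nrow(x) || window@startIndex < 1L)
    .configError("window outside recording")
  seg <- x[window@startIndex:(window@endIndex - 1L), , drop = FALSE]
  lay <- gridLayoutOf(recording)
  ok <- .validGrid(lay)
  nm <- channelNames(recording)
  pairRMS <- numeric(0)
  for (cc in seq_len(lay@nCols) - 1L) {
    for (rr in seq_len(lay@nRows - 1L) - 1L) {
      if (ok[rr + 1L, cc + 1L] && ok[rr + 2L, cc + 1L]) {
        a <- match(sprintf("r%dc%d", rr, cc), nm)
        b <- match(sprintf("r%dc%d", rr + 1L, cc), nm)
        pairRMS <- c(pairRMS, .rms(seg[, a] - seg[, b]))
      }
    }
  }
  if (length(pairRMS) == 0L)
    .configError("layout has no adjacent valid electrode pair along the fiber axis")
  floored <- FALSE
  eps <- .Machine$double.eps
  if (aggregate == "log-of-mean") {
    m <- mean(pairRMS)
    if (m <= 0) { m <- eps; floored <- TRUE }
    di <- log10(m)
  } else {
    if (any(pairRMS <= 0)) { pairRMS[pairRMS <= 0] <- eps; floored <- TRUE }
    di <- mean(log10(pairRMS))
  }
  structure(di, nPairs = length(pairRMS), floored = floored)
}

#' @rdname modifiedEntropy
#' @export
setMethod("modifiedEntropy", "ActivationMap", function(x) {
  v <- .validValues(x)
  if (length(v) < 1L) .configError("map has no valid channel")
  tot <- sum(v^2)
  if (tot <= 0)
    .gridEMGStop("gridEMG_undefined_entropy",
                 "undefined entropy: all channels are zero")
  p2 <- v^2 / tot
  nz <- p2 > 0            # 0 * log2(0) == 0 by convention
  -sum(p2[nz] * log2(p2[nz]))
})

#' @rdname mapCoV
#' @export
setMethod("mapCoV", "ActivationMap",
          function(x, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  v <- .validValues(x)
  if (length(v) < 2L)
    .gridEMGStop("gridEMG_undefined_cov",
                 "CoV undefined for fewer than two valid channels")
  m <- mean(v)
  if (m <= 0)
    .gridEMGStop("gridEMG_undefined_cov",
                 "undefined CoV: map mean is zero")
  s <- stats::sd(v)
  if (sdType == "population")
    s <- s * sqrt((length(v) - 1) / length(v))
  100 * s / m
})

#' @rdname meanRMS
#' @export
setMethod("meanRMS", "ActivationMap", function(x) {
  if (!isNormalized(x))
    .configError("meanRMS requires a map normalized to MVC")
  v <- .validValues(x)
  if (length(v) < 1L) .configError("map has no valid channel")
  mean(v)
})

#' Compute the full spatial feature set of a trial window
#'
#' Convenience wrapper composing the five per-trial features: intensity and
#' differential intensity from the raw map/signals, modified entropy and CoV
#' from the (scale-invariant) map, and mean RMS from the MVC-normalized map
#' when a reference is supplied.
#'
#' @param recording a band-pass filtered [EMGRecording-class].
#' @param window a [TrialWindow-class]; \code{NULL} = whole recording.
#' @param mvc optional [MVCReference-class]; without it \code{meanRMS} is
#'   \code{NA}.
#' @param diAggregate passed to [differentialIntensity()].
#' @param covSdType passed to [mapCoV()].
#' @return a [SpatialFeatures-class].
#' @export
spatialFeatures <- function(recording, window = NULL, mvc = NULL,
                            diAggregate = "log-of-mean",
                            covSdType = "sample") {
  map <- buildActivationMap(recording, window)
  di <- differentialIntensity(recording, window, aggregate = diAggregate)
  flags <- character(0)
  if (isTRUE(attr(di, "floored"))) flags <- c(flags, "floored_di")
  mr <- NA_real_
  if (!is.null(mvc))
    mr <- meanRMS(normalizeMap(map, mvc))
  new("SpatialFeatures",
      intensity = mapIntensity(map),
      differentialIntensity = as.numeric(di),
      meanRMS = mr,
      entropy = modifiedEntropy(map),
      cov = mapCoV(map, sdType = covSdType),
      nChannelsUsed = nChannels(map),
      flags = flags)
}
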