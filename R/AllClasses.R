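#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## GridLayout
## ---------------------------------------------------------------------------

#' Electrode grid geometry
#'
#' Describes a rectangular HDEMG electrode grid: its dimensions, which
#' positions carry no electrode, the axis running parallel to the muscle
#' fibers, and the interelectrode distance. The default layout is the
#' 8-row x 4-column semi-disposable grid with the upper-right corner
#' electrode absent (31 valid electrodes, 8 mm spacing), whose electrode
#' columns are oriented parallel to the fibers so that single-differential
#' pairs are formed between consecutive rows within a column.
#'
#' @slot nRows integer, number of grid rows.
#' @slot nCols integer, number of grid columns.
#' @slot missing integer matrix with columns \code{row}, \code{col} (0-based)
#'   listing positions without an electrode.
#' @slot fiberAxis \code{"row"}: the fiber direction runs along the row index
#'   within a column.
#' @slot interElectrodeDistance center-to-center spacing in mm (both
#'   directions).
#'
#' @seealso [gridLayout()]
#' @export
setClass("GridLayout",
  representation(
    nRows = "integer",
    nCols = "integer",
    missing = "matrix",
    fiberAxis = "character",
    interElectrodeDistance = "numeric"
  )
)

setValidity("GridLayout", function(object) {
  msgs <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msgs <- c(msgs, "grid must have at least one row and one column")
  m <- object@missing
  if (nrow(m) > 0) {
    if (ncol(m) != 2L)
      msgs <- c(msgs, "'missing' must have two columns (row, col)")
    else {
      if (any(m[, 1] < 0 | m[, 1] >= object@nRows |
              m[, 2] < 0 | m[, 2] >= object@nCols))
        msgs <- c(msgs, "missing electrode position outside the grid")
      if (anyDuplicated(paste(m[, 1], m[, 2])))
        msgs <- c(msgs, "duplicate missing electrode positions")
    }
  }
  if (!identical(object@fiberAxis, "row"))
    msgs <- c(msgs, "fiberAxis must be \"row\"")
  if (object@nRows * object@nCols - nrow(m) < 1L)
    msgs <- c(msgs, "layout must have at least one valid electrode")
  if (length(msgs)) msgs else TRUE
})

#' Construct an electrode grid layout
#'
#' @param nRows,nCols grid dimensions (default 8 x 4).
#' @param missing two-column matrix (or data.frame) of 0-based
#'   \code{(row, col)} positions without an electrode. The default marks the
#'   upper-right corner \code{(0, nCols - 1)} absent, giving the standard
#'   31-electrode grid.
#' @param interElectrodeDistance spacing in mm (default 8).
#' @return a [GridLayout-class].
#' @examples
#' layout <- gridLayout()
#' nChannels(layout)  # 31
#' @export
gridLayout <- function(nRows = 8L, nCols = 4L,
                       missing = cbind(0L, as.integer(nCols) - 1L),
                       interElectrodeDistance = 8) {
  if (is.null(missing)) missing <- matrix(integer(), 0L, 2L)
  missing <- as.matrix(missing)
  if (length(missing) == 0L) missing <- matrix(integer(), 0L, 2L)
  storage.mode(missing) <- "integer"
  colnames(missing) <- c("row", "col")
  new("GridLayout", nRows = as.integer(nRows), nCols = as.integer(nCols),
      missing = missing, fiberAxis = "row",
      interElectrodeDistance = interElectrodeDistance)
}

## ---------------------------------------------------------------------------
## EMGRecording
## ---------------------------------------------------------------------------

#' Multichannel monopolar surface-EMG recording
#'
#' A monopolar grid recording: one time series per valid electrode, a common
#' sampling rate, the electrode geometry, and trial metadata (participant,
#' sex, muscle, side, handle-design code, trial kind).
#'
#' @slot samples numeric matrix, rows = time samples, columns = valid
#'   channels in canonical order (see [channelNames()]).
#' @slot samplingRate sampling rate in Hz.
#' @slot layout the [GridLayout-class].
#' @slot meta named list of trial metadata.
#' @export
setClass("EMGRecording",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    layout = "GridLayout",
    meta = "list"
  )
)

setValidity("EMGRecording", function(object) {
  msgs <- character()
  if (object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be positive")
  want <- channelNames(object@layout)
  if (ncol(object@samples) != length(want))
    msgs <- c(msgs, sprintf(
      "channel count (%d) must equal layout valid-electrode count (%d)",
      ncol(object@samples), length(want)))
  else if (!is.null(colnames(object@samples)) &&
           !identical(colnames(object@samples), want))
    msgs <- c(msgs, "channel names do not match the layout's canonical order")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EMG recording
#'
#' @param samples numeric matrix (time x channels) in canonical channel order.
#' @param samplingRate sampling rate in Hz.
#' @param layout a [GridLayout-class] (default [gridLayout()]).
#' @param meta named list of trial metadata.
#' @return an [EMGRecording-class].
#' @export
emgRecording <- function(samples, samplingRate = 1000,
                         layout = gridLayout(), meta = list()) {
  samples <- as.matrix(samples)
  nm <- channelNames(layout)
  if (ncol(samples) == length(nm)) colnames(samples) <- nm
  new("EMGRecording", samples = samples, samplingRate = as.numeric(samplingRate),
      layout = layout, meta = meta)
}

## ---------------------------------------------------------------------------
## ForceTrace
## ---------------------------------------------------------------------------

#' Hand-force trace
#'
#' The push force applied to the cart handle, in newtons, sampled on the same
#' clock as the paired EMG recording.
#'
#' @slot force numeric vector of force samples (N).
#' @slot samplingRate sampling rate in Hz.
#' @export
setClass("ForceTrace",
  representation(force = "numeric", samplingRate = "numeric")
)

setValidity("ForceTrace", function(object) {
  msgs <- character()
  if (object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be positive")
  if (any(!is.finite(object@force)))
    msgs <- c(msgs, "force values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a force trace
#' @param force numeric vector of force samples in newtons.
#' @param samplingRate sampling rate in Hz.
#' @return a [ForceTrace-class].
#' @export
forceTrace <- function(force, samplingRate = 1000) {
  new("ForceTrace", force = as.numeric(force),
      samplingRate = as.numeric(samplingRate))
}

## ---------------------------------------------------------------------------
## TrialWindow
## ---------------------------------------------------------------------------

#' Analysis window within a trial
#'
#' A half-open sample-index interval \code{[startIndex, endIndex)} (1-based)
#' identifying the analysis window of a trial, typically the 0.5 s
#' push-initiation window following the 20 N force crossing.
#'
#' @slot startIndex first sample in the window (1-based).
#' @slot endIndex one past the last sample.
#' @slot samplingRate sampling rate in Hz (for duration bookkeeping).
#' @export
setClass("TrialWindow",
  representation(startIndex = "integer", endIndex = "integer",
                 samplingRate = "numeric")
)

setValidity("TrialWindow", function(object) {
  if (object@endIndex <= object@startIndex)
    "window must contain at least one sample"
  else if (object@startIndex < 1L)
    "startIndex must be >= 1"
  else TRUE
})

#' Construct a trial window
#' @param startIndex first sample (1-based).
#' @param endIndex one past the last sample (half-open interval).
#' @param samplingRate sampling rate in Hz.
#' @return a [TrialWindow-class].
#' @export
trialWindow <- function(startIndex, endIndex, samplingRate = 1000) {
  new("TrialWindow", startIndex = as.integer(startIndex),
      endIndex = as.integer(endIndex), samplingRate = samplingRate)
}

## ---------------------------------------------------------------------------
## ActivationMap
## ---------------------------------------------------------------------------

#' RMS activation (heat intensity) map
#'
#' The 2-D array of per-electrode RMS amplitudes over an analysis window:
#' \eqn{HM_{i,j} = RMS(sEMG_{i,j})}. Missing electrodes carry \code{NA}.
#' The map may be raw (amplitude units) or normalized to the individual's
#' MVC reference (values are then fractions of MVC).
#'
#' @slot values numeric matrix (nRows x nCols), \code{NA} at missing
#'   positions.
#' @slot layout the [GridLayout-class].
#' @slot normalized logical: has the map been divided by an MVC reference?
#' @slot window provenance: the [TrialWindow-class] the map was computed
#'   over, or \code{NULL}.
#' @export
setClass("ActivationMap",
  representation(values = "matrix", layout = "GridLayout",
                 normalized = "logical", window = "ANY")
)

setValidity("ActivationMap", function(object) {
  msgs <- character()
  lay <- object@layout
  v <- object@values
  if (nrow(v) != lay@nRows || ncol(v) != lay@nCols)
    msgs <- c(msgs, "values matrix must match the grid dimensions")
  else {
    maskNA <- is.na(v)
    wantNA <- matrix(FALSE, lay@nRows, lay@nCols)
    if (nrow(lay@missing) > 0)
      wantNA[lay@missing + 1L] <- TRUE
    if (!identical(unname(maskNA), wantNA))
      msgs <- c(msgs, "NA pattern must match the layout's missing electrodes")
    if (any(v[!maskNA] < 0))
      msgs <- c(msgs, "map values must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an activation map
#'
#' @param values either a full grid matrix (nRows x nCols, \code{NA} at
#'   missing positions) or a vector of per-channel values in canonical
#'   channel order.
#' @param layout a [GridLayout-class].
#' @param normalized logical, is the map already expressed as fraction of MVC?
#' @param window optional [TrialWindow-class] provenance.
#' @return an [ActivationMap-class].
#' @examples
#' m <- activationMap(rep(10, 31))
#' mapIntensity(m)  # 1
#' @export
activationMap <- function(values, layout = gridLayout(), normalized = FALSE,
                          window = NULL) {
  if (!is.matrix(values)) {
    vc <- validChannels(layout)
    if (length(values) != nrow(vc))
      .configError(sprintf(
        "expected %d channel values for this layout, got %d",
        nrow(vc), length(values)))
    m <- matrix(NA_real_, layout@nRows, layout@nCols)
    m[cbind(vc$row + 1L, vc$col + 1L)] <- as.numeric(values)
    values <- m
  }
  new("ActivationMap", values = values, layout = layout,
      normalized = normalized, window = window)
}

## ---------------------------------------------------------------------------
## MVCReference
## ---------------------------------------------------------------------------

#' Per-channel MVC normalization reference
#'
#' For each valid electrode, the maximum RMS amplitude observed during
#' maximal voluntary contraction trials; dividing a task activation map by
#' this reference expresses it as a fraction of MVC.
#'
#' @slot values numeric grid matrix of reference RMS values (\code{NA} at
#'   missing positions), all valid entries strictly positive.
#' @slot layout the [GridLayout-class].
#' @slot muscle,side trial identity.
#' @export
setClass("MVCReference",
  representation(values = "matrix", layout = "GridLayout",
                 muscle = "character", side = "character")
)

setValidity("MVCReference", function(object) {
  v <- object@values[!is.na(object@values)]
  if (any(v <= 0)) "all MVC reference values must be strictly positive"
  else TRUE
})

## ---------------------------------------------------------------------------
## SpatialFeatures
## ---------------------------------------------------------------------------

#' Per-trial spatial feature set
#'
#' The five per-trial outputs of the spatial pipeline: intensity,
#' differential intensity, mean RMS (fraction of MVC), modified entropy and
#' coefficient of variation, plus the number of channels used and QC flags
#' (e.g. \code{"floored_di"} when all single-differential signals were zero).
#'
#' @slot intensity log10 a.u.
#' @slot differentialIntensity log10 a.u.
#' @slot meanRMS fraction of MVC (\code{NA} when no MVC reference given).
#' @slot entropy bits.
#' @slot cov percent.
#' @slot nChannelsUsed valid channel count of the underlying map.
#' @slot flags character vector of QC flags.
#' @export
setClass("SpatialFeatures",
  representation(intensity = "numeric", differentialIntensity = "numeric",
                 meanRMS = "numeric", entropy = "numeric", cov = "numeric",
                 nChannelsUsed = "integer", flags = "character")
)

#' Convert spatial features to a one-row data.frame
#'
#' @param x a [SpatialFeatures-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return one-row data.frame with columns \code{intensity},
#'   \code{differential_intensity}, \code{mean_rms_pct}, \code{entropy_bits},
#'   \code{cov_pct}, \code{n_channels}, \code{qc_flags}.
#' @export
as.data.frame.SpatialFeatures <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    intensity = x@intensity,
    differential_intensity = x@differentialIntensity,
    mean_rms_pct = 100 * x@meanRMS,
    entropy_bits = x@entropy,
    cov_pct = x@cov,
    n_channels = x@nChannelsUsed,
    qc_flags = paste(x@flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

## ---------------------------------------------------------------------------
## Simulation types
## ---------------------------------------------------------------------------

#' Source territory for the synthetic generator
#'
#' A spatial cluster of active muscle tissue under the grid, modelled as an
#' isotropic Gaussian amplitude profile: an electrode at grid distance d from
#' the territory center receives amplitude
#' \code{gain * exp(-d^2 / (2 * spread^2))}.
#'
#' @slot center numeric length-2, continuous \code{(row, col)} grid
#'   coordinates (0-based).
#' @slot spread isotropic spatial SD in electrode units, > 0.
#' @slot gain dimensionless amplitude multiplier, >= 0.
#' @export
setClass("SourceTerritory",
  representation(center = "numeric", spread = "numeric", gain = "numeric")
)

setValidity("SourceTerritory", function(object) {
  msgs <- character()
  if (length(object@center) != 2L)
    msgs <- c(msgs, "center must be (row, col)")
  if (object@spread <= 0) msgs <- c(msgs, "spread must be > 0")
  if (object@gain < 0) msgs <- c(msgs, "gain must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a source territory
#' @param center continuous (row, col) grid coordinates, 0-based.
#' @param spread isotropic spatial SD in electrode units.
#' @param gain amplitude multiplier.
#' @return a [SourceTerritory-class].
#' @export
sourceTerritory <- function(center, spread, gain = 1) {
  new("SourceTerritory", center = as.numeric(center), spread = spread,
      gain = gain)
}

#' Simulation configuration for a single synthetic trial
#'
#' Parameters for one synthetic grid-EMG trial and its paired force trace.
#' Defaults mirror the recording conditions emulated by the package: 1000 Hz
#' sampling with a 10-500 Hz bandwidth.
#'
#' @slot duration trial length in seconds.
#' @slot samplingRate Hz.
#' @slot band numeric length-2 (low, high) band edges in Hz.
#' @slot territories list of [SourceTerritory-class]; empty means "derive a
#'   single territory from \code{clustering}" (see [clusteringToSpread()]).
#' @slot noiseSd additive per-channel noise RMS, signal units.
#' @slot clustering scalar in [0, 1]: 0 = spatially uniform activation,
#'   1 = single tight territory.
#' @slot onsetTime time (s) at which the force crosses 20 N.
#' @slot forcePlateau plateau force in newtons.
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
  representation(duration = "numeric", samplingRate = "numeric",
                 band = "numeric", territories = "list", noiseSd = "numeric",
                 clustering = "numeric", onsetTime = "numeric",
                 forcePlateau = "numeric", seed = "integer")
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@duration <= 0) msgs <- c(msgs, "duration must be > 0")
  if (object@samplingRate <= 0) msgs <- c(msgs, "samplingRate must be > 0")
  b <- object@band
  if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1] ||
      b[1] >= object@samplingRate / 2)
    msgs <- c(msgs, "band must satisfy 0 < low < high, low < Nyquist")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@clustering < 0 || object@clustering > 1)
    msgs <- c(msgs, "clustering must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param duration trial length in seconds.
#' @param samplingRate sampling rate in Hz.
#' @param band (low, high) band edges in Hz.
#' @param territories list of [SourceTerritory-class]; when empty, a single
#'   territory at the grid center with spread
#'   \code{clusteringToSpread(clustering)} and gain 1 is used.
#' @param noiseSd additive channel-noise RMS in signal units.
#' @param clustering spatial clustering of activation in [0, 1].
#' @param onsetTime force-onset time in seconds.
#' @param forcePlateau plateau force in newtons.
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @export
simConfig <- function(duration = 3, samplingRate = 1000, band = c(10, 500),
                      territories = list(), noiseSd = 0.05, clustering = 0,
                      onsetTime = 1, forcePlateau = 100, seed = 1L) {
  new("SimulationConfig", duration = duration, samplingRate = samplingRate,
      band = as.numeric(band), territories = territories, noiseSd = noiseSd,
      clustering = clustering, onsetTime = onsetTime,
      forcePlateau = forcePlateau, seed = as.integer(seed))
}

#' Multi-participant synthetic study design
#'
#' Describes a full synthetic pushing study: participants, the six handle
#' designs (height H = hip / S = shoulder, then orientation H = horizontal /
#' S = semi-pronated / V = vertical), the three bilateral trunk muscles
#' (ES = erector spinae, EO = external oblique, RA = rectus abdominis), and
#' a per-design effect table of multiplicative shifts on mean activation
#' (\code{gain}) and spatial clustering (\code{clustering}).
#'
#' @slot nParticipants participant count.
#' @slot designs character(6) handle-design codes.
#' @slot muscles character(3) muscle codes.
#' @slot sides character(2).
#' @slot effectTable data.frame with columns \code{design}, \code{gain},
#'   \code{clustering}: ground-truth per-design effects.
#' @slot baseConfig the per-trial [SimulationConfig-class] template.
#' @slot mvcAmplitude mean per-channel MVC RMS amplitude (signal units).
#' @slot seed study-level RNG seed.
#' @export
setClass("StudyDesign",
  representation(nParticipants = "integer", designs = "character",
                 muscles = "character", sides = "character",
                 effectTable = "data.frame", baseConfig = "SimulationConfig",
                 mvcAmplitude = "numeric", seed = "integer")
)

setValidity("StudyDesign", function(object) {
  msgs <- character()
  if (length(object@designs) != 6L)
    msgs <- c(msgs, "designs must have exactly 6 entries")
  if (length(object@muscles) != 3L)
    msgs <- c(msgs, "muscles must have exactly 3 entries")
  if (length(object@sides) != 2L)
    msgs <- c(msgs, "sides must have exactly 2 entries")
  if (!all(c("design", "gain", "clustering") %in% names(object@effectTable)))
    msgs <- c(msgs, "effectTable needs columns design, gain, clustering")
  else if (!all(object@designs %in% object@effectTable$design))
    msgs <- c(msgs, "effectTable must cover every design")
  if (object@nParticipants < 1L)
    msgs <- c(msgs, "need at least one participant")
  if (length(msgs)) msgs else TRUE
})

#' Default per-design effect table
#'
#' Ground-truth effects emulating the study's qualitative findings: pushing
#' at hip height with a horizontal handle (HH) yields the lowest mean
#' activation and the most homogeneous (least clustered) maps, while the
#' shoulder-height semi-pronated/vertical designs (SS, SV) are the most
#' clustered.
#'
#' @return data.frame with columns \code{design}, \code{gain} (multiplier on
#'   mean activation amplitude) and \code{clustering} (spatial clustering in
#'   [0, 1]).
#' @export
defaultEffectTable <- function() {
  data.frame(
    design = c("HH", "HS", "HV", "SH", "SS", "SV"),
    gain = c(0.60, 1.00, 1.05, 1.00, 1.10, 1.15),
    clustering = c(0.25, 0.45, 0.45, 0.50, 0.65, 0.65),
    stringsAsFactors = FALSE
  )
}

#' Construct a study design
#'
#' @param nParticipants number of participants.
#' @param designs the six handle-design codes.
#' @param muscles the three bilateral trunk muscles.
#' @param sides body sides.
#' @param effectTable per-design ground-truth effects
#'   (default [defaultEffectTable()]); an identity table (all gains 1, equal
#'   clustering) makes designs statistically exchangeable.
#' @param baseConfig per-trial simulation template.
#' @param mvcAmplitude mean per-channel MVC RMS (signal units). The default
#'   of 10 against a task gain of ~1 puts task activity near 10% MVC.
#' @param seed study seed.
#' @return a [StudyDesign-class].
#' @export
studyDesign <- function(nParticipants = 20,
                        designs = c("HH", "HS", "HV", "SH", "SS", "SV"),
                        muscles = c("ES", "EO", "RA"),
                        sides = c("left", "right"),
                        effectTable = defaultEffectTable(),
                        baseConfig = simConfig(),
                        mvcAmplitude = 10,
                        seed = 1L) {
  new("StudyDesign", nParticipants = as.integer(nParticipants),
      designs = designs, muscles = muscles, sides = sides,
      effectTable = effectTable, baseConfig = baseConfig,
      mvcAmplitude = mvcAmplitude, seed = as.integer(seed))
}

#' A simulated study: trial bundles plus the generating design
#'
#' Container returned by [generateStudy()]. Each bundle is one recording
#' trial (participant x muscle pair x design) holding both sides' EMG
#' recordings, the shared force trace, per-side MVC trial sets and metadata.
#'
#' @slot bundles list of trial bundles.
#' @slot design the generating [StudyDesign-class].
#' @export
setClass("EMGStudy",
  representation(bundles = "list", design = "StudyDesign")
)

#' @describeIn EMGStudy-class number of trial bundles.
#' @param x an \code{EMGStudy}.
#' @export
setMethod("length", "EMGStudy", function(x) length(x@bundles))

#' Extract a trial bundle
#' @param x an [EMGStudy-class].
#' @param i bundle index.
#' @param j,... unused.
#' @param exact unused.
#' @return the bundle: a list with elements \code{recordings} (per side),
#'   \code{force}, \code{mvc} (per side), \code{meta}.
#' @export
setMethod("[[", "EMGStudy", function(x, i, j, ...) x@bundles[[i]])
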