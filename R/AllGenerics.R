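#' @include errors.R
NULL

#' Number of valid channels
#'
#' @param x a [GridLayout-class], [EMGRecording-class] or [ActivationMap-class].
#' @return integer count of valid (non-missing) electrodes.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Channel names in canonical order
#'
#' Channels are ordered column-major over the grid (grid column 0 rows 0..7,
#' then column 1, ...), skipping missing electrodes, and named
#' \code{"r<row>c<col>"} with 0-based grid indices.
#'
#' @param x a [GridLayout-class] or object carrying one.
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Valid electrode positions
#'
#' @param x a [GridLayout-class] or object carrying one.
#' @return data.frame with columns \code{row}, \code{col} (0-based) and
#'   \code{name}, one row per valid electrode, canonical channel order.
#' @export
setGeneric("validChannels", function(x) standardGeneric("validChannels"))

#' Sampling rate accessor
#' @param x an object with a time base.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Sample matrix accessor
#' @param x an [EMGRecording-class].
#' @return numeric matrix, rows = time samples, columns = valid channels.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' Grid layout accessor
#' @param x an object carrying a [GridLayout-class].
#' @return the [GridLayout-class].
#' @export
setGeneric("gridLayoutOf", function(x) standardGeneric("gridLayoutOf"))

#' Trial metadata accessor
#' @param x an [EMGRecording-class].
#' @return named list of trial metadata.
#' @export
setGeneric("metaData", function(x) standardGeneric("metaData"))

#' Force samples accessor
#' @param x a [ForceTrace-class].
#' @return numeric vector of force values in newtons.
#' @export
setGeneric("forceValues", function(x) standardGeneric("forceValues"))

#' Activation-map values
#' @param x an [ActivationMap-class] or [MVCReference-class].
#' @return numeric grid matrix (rows x cols) with \code{NA} at missing
#'   electrodes.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Is a map normalized to MVC?
#' @param x an [ActivationMap-class].
#' @return logical flag.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' Map intensity: common logarithm of the mean map amplitude
#'
#' The intensity feature \eqn{I = \log_{10}((1/N)\sum_{i,j} HM_{i,j})}, the
#' common logarithm of the mean RMS amplitude over the \eqn{N} valid channels
#' of an activation map. Log-compression is used because the EMG
#' amplitude-force relation is nonlinear.
#'
#' @param x an [ActivationMap-class].
#' @return intensity in log10 arbitrary units.
#' @export
setGeneric("mapIntensity", function(x) standardGeneric("mapIntensity"))

#' Modified entropy of an activation map
#'
#' Shannon-style entropy of the normalized channel powers
#' \eqn{E = -\sum_i p_i^2 \log_2 p_i^2} with
#' \eqn{p_i^2 = HM_i^2 / \sum_j HM_j^2} over the valid channels. Maximal
#' (\eqn{\log_2 N}) when all channels share one RMS value; 0 when exactly one
#' channel is active. High entropy reads as spatially homogeneous activation,
#' low entropy as clustered activation.
#'
#' @param x an [ActivationMap-class].
#' @return entropy in bits.
#' @export
setGeneric("modifiedEntropy", function(x) standardGeneric("modifiedEntropy"))

#' Coefficient of variation of an activation map
#'
#' \eqn{CoV = 100 \cdot SD / mean} over the valid channel RMS values; a
#' spatial-heterogeneity index complementary to [modifiedEntropy()].
#'
#' @param x an [ActivationMap-class].
#' @param sdType \code{"sample"} (N-1 denominator, default) or
#'   \code{"population"}.
#' @return CoV in percent.
#' @export
setGeneric("mapCoV", function(x, sdType = c("sample", "population"))
  standardGeneric("mapCoV"))

#' Mean RMS of a normalized activation map
#'
#' Arithmetic mean of the valid channel values of an MVC-normalized map,
#' i.e. the grid-average muscle activity as a fraction of MVC.
#'
#' @param x an [ActivationMap-class]; must be normalized.
#' @return mean RMS as a fraction of MVC (multiply by 100 for %MVC).
#' @export
setGeneric("meanRMS", function(x) standardGeneric("meanRMS"))
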