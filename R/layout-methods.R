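#' @include AllClasses.R
NULL

## Canonical channel order: column-major over the grid (column 0 rows 0..7,
## then column 1, ...), skipping missing electrodes. Single-differential
## pairs along the fiber axis are then consecutive entries within a column.

.validGrid <- function(layout) {
  ok <- matrix(TRUE, layout@nRows, layout@nCols)
  if (nrow(layout@missing) > 0)
    ok[layout@missing + 1L] <- FALSE
  ok
}

#' @rdname validChannels
#' @export
setMethod("validChannels", "GridLayout", function(x) {
  ok <- .validGrid(x)
  out <- expand.grid(row = seq_len(x@nRows) - 1L, col = seq_len(x@nCols) - 1L)
  out <- out[ok[cbind(out$row + 1L, out$col + 1L)], , drop = FALSE]
  out$name <- sprintf("r%dc%d", out$row, out$col)
  rownames(out) <- NULL
  out
})

#' @rdname nChannels
#' @export
setMethod("nChannels", "GridLayout", function(x)
  x@nRows * x@nCols - nrow(x@missing))

#' @rdname channelNames
#' @export
setMethod("channelNames", "GridLayout", function(x) validChannels(x)$name)

#' @rdname nChannels
#' @export
setMethod("nChannels", "EMGRecording", function(x) ncol(x@samples))

#' @rdname channelNames
#' @export
setMethod("channelNames", "EMGRecording", function(x) colnames(x@samples))

#' @rdname samples
#' @export
setMethod("samples", "EMGRecording", function(x) x@samples)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EMGRecording", function(x) x@samplingRate)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ForceTrace", function(x) x@samplingRate)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TrialWindow", function(x) x@samplingRate)

#' @rdname gridLayoutOf
#' @export
setMethod("gridLayoutOf", "EMGRecording", function(x) x@layout)

#' @rdname gridLayoutOf
#' @export
setMethod("gridLayoutOf", "ActivationMap", function(x) x@layout)

#' @rdname gridLayoutOf
#' @export
setMethod("gridLayoutOf", "MVCReference", function(x) x@layout)

#' @rdname metaData
#' @export
setMethod("metaData", "EMGRecording", function(x) x@meta)

#' @rdname forceValues
#' @export
setMethod("forceValues", "ForceTrace", function(x) x@force)

#' @rdname mapValues
#' @export
setMethod("mapValues", "ActivationMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("mapValues", "MVCReference", function(x) x@values)

#' @rdname isNormalized
#' @export
setMethod("isNormalized", "ActivationMap", function(x) x@normalized)

#' @rdname nChannels
#' @export
setMethod("nChannels", "ActivationMap", function(x)
  sum(!is.na(x@values)))

## -- show methods -----------------------------------------------------------

setMethod("show", "GridLayout", function(object) {
  cat(sprintf("GridLayout: %d x %d grid, %d valid electrodes, %g mm spacing\n",
              object@nRows, object@nCols, nChannels(object),
              object@interElectrodeDistance))
  if (nrow(object@missing) > 0)
    cat("  missing:",
        paste(sprintf("(%d,%d)", object@missing[, 1], object@missing[, 2]),
              collapse = " "), "\n")
})

setMethod("show", "EMGRecording", function(object) {
  cat(sprintf("EMGRecording: %d channels x %d samples @ %g Hz (%.2f s)\n",
              ncol(object@samples), nrow(object@samples),
              object@samplingRate,
              nrow(object@samples) / object@samplingRate))
  m <- object@meta
  if (length(m))
    cat("  meta:", paste(names(m), unlist(lapply(m, format)), sep = "=",
                         collapse = ", "), "\n")
})

setMethod("show", "ForceTrace", function(object) {
  cat(sprintf("ForceTrace: %d samples @ %g Hz, peak %.1f N\n",
              length(object@force), object@samplingRate,
              max(object@force)))
})

setMethod("show", "TrialWindow", function(object) {
  cat(sprintf("TrialWindow: samples [%d, %d) (%.3f s @ %g Hz)\n",
              object@startIndex, object@endIndex,
              (object@endIndex - object@startIndex) / object@samplingRate,
              object@samplingRate))
})

setMethod("show", "ActivationMap", function(object) {
  cat(sprintf("ActivationMap: %d x %d grid, %d valid channels, %s\n",
              nrow(object@values), ncol(object@values), nChannels(object),
              if (object@normalized) "normalized (fraction of MVC)"
              else "raw amplitude"))
  v <- object@values[!is.na(object@values)]
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
})

setMethod("show", "SpatialFeatures", function(object) {
  cat("SpatialFeatures:\n")
  cat(sprintf("  intensity              %8.4f  (log10 a.u.)\n", object@intensity))
  cat(sprintf("  differential intensity %8.4f  (log10 a.u.)\n",
              object@differentialIntensity))
  cat(sprintf("  mean RMS               %8.2f  %%MVC\n", 100 * object@meanRMS))
  cat(sprintf("  modified entropy       %8.4f  bits\n", object@entropy))
  cat(sprintf("  CoV                    %8.2f  %%\n", object@cov))
  cat(sprintf("  channels used          %8d\n", object@nChannelsUsed))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "EMGStudy", function(object) {
  d <- object@design
  cat(sprintf(
    "EMGStudy: %d trial bundles (%d participants x %d designs x %d muscles)\n",
    length(object@bundles), d@nParticipants, length(d@designs),
    length(d@muscles)))
})

#' Plot an activation map as a heat map
#'
#' Renders the grid RMS map with a blue-to-red colormap (low to high
#' activation), rows top-down as the grid is placed on the muscle.
#'
#' @param map an [ActivationMap-class].
#' @param zlim color scale limits; defaults to \code{c(0, max)} of the map.
#'   To scale a map to the individual's MVC, pass \code{c(0, 1)} for a
#'   normalized map.
#' @param main plot title.
#' @return invisibly, the matrix as drawn.
#' @export
plotMap <- function(map, zlim = NULL, main = "") {
  v <- mapValues(map)
  if (is.null(zlim)) zlim <- c(0, max(v, na.rm = TRUE))
  pal <- grDevices::colorRampPalette(
    c("darkblue", "blue", "cyan", "yellow", "red", "darkred"))(64)
  ## image() draws x right, y up; transpose and flip rows so row 0 is on top
  z <- t(v[rev(seq_len(nrow(v))), , drop = FALSE])
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z, zlim = zlim,
                  col = pal, xlab = "grid column", ylab = "grid row",
                  axes = FALSE, main = main)
  graphics::axis(1, at = seq_len(nrow(z)), labels = seq_len(nrow(z)) - 1L)
  graphics::axis(2, at = seq_len(ncol(z)), labels = rev(seq_len(ncol(z)) - 1L))
  invisible(z)
}
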