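#' @include AllClasses.R
NULL

## Zero-phase band-pass filtering.
##
## The filter is a 4th-order digital Butterworth band-pass designed with
## signal::butter() and applied forward-backward (zero phase), i.e. with the
## squared magnitude response |H(w)|^2 and no phase shift, so the analysis
## window stays aligned with the force clock. The forward-backward pass is
## carried out in the frequency domain (spectrum x |H(w)|^2), the
## circular-boundary equivalent of time-domain filtfilt, which vectorizes
## across all grid channels at once.

.clampHigh <- function(high, fs) {
  nyq <- fs / 2
  ## a high edge at (or beyond) Nyquist is clamped just below it; with
  ## acquisition hardware already low-passing at the Nyquist edge this is a
  ## formality (499 Hz at fs = 1000)
  min(high, 0.998 * nyq)
}

.checkBand <- function(low, high, fs) {
  high <- .clampHigh(high, fs)
  if (!(low > 0 && low < high && high < fs / 2))
    .configError(sprintf(
      "invalid band [%g, %g] Hz for sampling rate %g Hz", low, high, fs))
  c(low, high)
}

## |H(w)|^2 of the 4th-order Butterworth band-pass at the n FFT bin
## frequencies for sampling rate fs.
.butterMagSq <- function(n, fs, low, high, order = 4) {
  ba <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1) / n
  z <- exp(-1i * w)
  num <- Reduce(function(acc, coef) acc * z + coef, ba$b, accumulate = FALSE)
  den <- Reduce(function(acc, coef) acc * z + coef, ba$a, accumulate = FALSE)
  Mod(num / den)^2
}

## Zero-phase band-pass of a sample matrix (time x channels).
.zeroPhaseBandpass <- function(x, fs, low, high, order = 4) {
  x <- as.matrix(x)
  n <- nrow(x)
  h2 <- .butterMagSq(n, fs, low, high, order)
  X <- stats::mvfft(x)
  Re(stats::mvfft(X * h2, inverse = TRUE)) / n
}

#' Band-pass filter a grid recording
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' identically to every channel. The default 10-500 Hz band matches the
#' recording bandwidth of the emulated acquisition chain; at a 1000 Hz
#' sampling rate the 500 Hz edge sits at Nyquist and is clamped to 499 Hz.
#'
#' @param recording an [EMGRecording-class].
#' @param low,high band edges in Hz.
#' @return an [EMGRecording-class] of identical dimensions with filtered
#'   samples; metadata gains a \code{filter} entry recording the settings.
#' @examples
#' rec <- generateGridEMG(simConfig(duration = 1))
#' filt <- bandpassRecording(rec)
#' @export
bandpassRecording <- function(recording, low = 10, high = 500) {
  fs <- samplingRate(recording)
  band <- .checkBand(low, high, fs)
  y <- .zeroPhaseBandpass(samples(recording), fs, band[1], band[2])
  colnames(y) <- channelNames(recording)
  meta <- metaData(recording)
  meta$filter <- list(type = "butterworth", order = 4, zero_phase = TRUE,
                      low_hz = band[1], high_hz = band[2])
  emgRecording(y, samplingRate = fs, layout = gridLayoutOf(recording),
               meta = meta)
}
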