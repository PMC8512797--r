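#' @include filter.R
NULL

## Synthetic grid-EMG generator.
##
## Source model: each SourceTerritory drives one band-limited Gaussian noise
## process shared across the grid, received by electrode e with spatial
## weight w_t(e) = gain_t * exp(-d(e, center_t)^2 / (2 * spread_t^2)).
## Territories are mutually independent, and each channel additionally
## carries independent band-limited noise of RMS noiseSd, so the per-channel
## RMS is sqrt(sum_t w_t(e)^2 + noiseSd^2) (quadrature sum). Edge transients
## of the band-limiting filter are handled by generating 0.25 s of extra
## signal at each end and discarding it, so stated durations are clean.

.SPREAD_MAX <- 25
.SPREAD_MIN <- 0.8

#' Map the clustering parameter to a territory spread
#'
#' The simulator's \code{clustering} scalar maps linearly onto the spatial
#' SD of the derived source territory:
#' \code{spread = (1 - clustering) * 25 + clustering * 0.8} electrode units.
#' At clustering 0 the territory is far wider than the grid (near-uniform
#' weights, within ~1% across the default grid); at clustering 1 it is a
#' tight sub-electrode cluster. The formula is exported so tests can invert
#' it.
#'
#' @param clustering scalar in [0, 1].
#' @return territory spread in electrode units.
#' @export
clusteringToSpread <- function(clustering) {
  stopifnot(clustering >= 0, clustering <= 1)
  (1 - clustering) * .SPREAD_MAX + clustering * .SPREAD_MIN
}

## Territories of a config: explicit list, or one derived from clustering
## centered on the grid.
.configTerritories <- function(config, layout) {
  if (length(config@territories) > 0) return(config@territories)
  list(sourceTerritory(
    center = c((layout@nRows - 1) / 2, (layout@nCols - 1) / 2),
    spread = clusteringToSpread(config@clustering),
    gain = 1))
}

#' Spatial weights of territories at the valid electrodes
#'
#' @param territories list of [SourceTerritory-class].
#' @param layout a [GridLayout-class].
#' @return matrix, rows = valid channels (canonical order), one column per
#'   territory, entries \code{gain * exp(-d^2 / (2 spread^2))}.
#' @export
territoryWeights <- function(territories, layout) {
  vc <- validChannels(layout)
  w <- vapply(territories, function(tt) {
    d2 <- (vc$row - tt@center[1])^2 + (vc$col - tt@center[2])^2
    tt@gain * exp(-d2 / (2 * tt@spread^2))
  }, numeric(nrow(vc)))
  matrix(w, nrow = nrow(vc),
         dimnames = list(vc$name, NULL))
}

## Band-limited unit-RMS noise columns: white Gaussian noise, zero-phase
## Butterworth band-pass, edge-trimmed, each column rescaled to unit RMS.
.bandlimitedNoise <- function(nOut, nCols, fs, band) {
  pad <- round(0.25 * fs)
  x <- matrix(stats::rnorm((nOut + 2 * pad) * nCols), ncol = nCols)
  band <- .checkBand(band[1], band[2], fs)
  y <- .zeroPhaseBandpass(x, fs, band[1], band[2])
  y <- y[(pad + 1):(pad + nOut), , drop = FALSE]
  rms <- sqrt(colMeans(y^2))
  sweep(y, 2, ifelse(rms > 0, rms, 1), "/")
}

#' Generate a synthetic grid-EMG trial
#'
#' Produces one multichannel monopolar recording with known ground-truth
#' spatial structure: band-limited zero-mean channels whose RMS amplitudes
#' follow the territory weight profile, \eqn{RMS(e)^2 = \sum_t w_t(e)^2 +
#' noiseSd^2}. Deterministic given the seed.
#'
#' @param config a [SimulationConfig-class].
#' @param layout a [GridLayout-class] (default: the standard 31-electrode
#'   grid).
#' @param seed RNG seed; defaults to \code{config@seed}.
#' @param meta extra metadata merged into the recording.
#' @return an [EMGRecording-class].
#' @examples
#' rec <- generateGridEMG(simConfig(duration = 1, clustering = 0.8))
#' @export
generateGridEMG <- function(config, layout = gridLayout(),
                            seed = config@seed, meta = list()) {
  validObject(config)
  validObject(layout)
  if (nChannels(layout) < 1L) .configError("layout has no valid electrode")
  fs <- config@samplingRate
  n <- round(config@duration * fs)
  terr <- .configTerritories(config, layout)
  w <- territoryWeights(terr, layout)
  nch <- nrow(w)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  ## one unit-RMS source per territory, shared across the grid
  src <- .bandlimitedNoise(n, length(terr), fs, config@band)
  out <- src %*% t(w)
  if (config@noiseSd > 0)
    out <- out + config@noiseSd * .bandlimitedNoise(n, nch, fs, config@band)
  colnames(out) <- rownames(w)
  meta <- utils::modifyList(
    list(kind = "push", seed = as.integer(seed),
         ground_truth = list(clustering = config@clustering,
                             noise_sd = config@noiseSd)),
    meta)
  emgRecording(out, samplingRate = fs, layout = layout, meta = meta)
}

#' Generate a synthetic hand-force trace
#'
#' Builds a deterministic force profile that stays below the 20 N initiation
#' threshold before \code{onsetTime}, rises linearly through 20 N exactly at
#' \code{onsetTime} (at 200 N/s), and plateaus at \code{forcePlateau}. A
#' plateau at or below 20 N never crosses the threshold (useful for testing
#' the no-initiation path). Optional measurement noise is added everywhere
#' but clipped below the threshold prior to onset so the crossing time is
#' preserved.
#'
#' @param config a [SimulationConfig-class] (uses \code{duration},
#'   \code{samplingRate}, \code{onsetTime}, \code{forcePlateau}).
#' @param seed RNG seed (only used when \code{noiseSdN > 0}).
#' @param noiseSdN measurement-noise SD in newtons (default 0).
#' @return a [ForceTrace-class].
#' @export
generateForceTrace <- function(config, seed = config@seed, noiseSdN = 0) {
  validObject(config)
  fs <- config@samplingRate
  slope <- 200  # N/s rise rate through the threshold
  if (config@onsetTime + 0.5 > config@duration)
    .configError("onsetTime too close to the end of the trace (need 0.5 s after onset)")
  if (config@onsetTime < 20 / slope)
    .configError(sprintf("onsetTime must be >= %.2f s", 20 / slope))
  n <- round(config@duration * fs)
  t <- (seq_len(n) - 1) / fs
  tStart <- config@onsetTime - 20 / slope
  f <- pmin(pmax(slope * (t - tStart), 0), config@forcePlateau)
  if (noiseSdN > 0) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    f <- f + stats::rnorm(n, sd = noiseSdN)
    pre <- t < config@onsetTime
    f[pre] <- pmin(pmax(f[pre], 0), 19.5)
  }
  forceTrace(f, samplingRate = fs)
}

#' Generate synthetic MVC calibration trials
#'
#' Produces maximal-contraction calibration recordings (by default three
#' five-second trials) whose per-channel RMS is centered on the requested
#' amplitude. Deterministic given the seed.
#'
#' @param layout a [GridLayout-class].
#' @param amplitude scalar or per-channel vector of true MVC RMS amplitudes
#'   (signal units), strictly positive.
#' @param seed RNG seed.
#' @param nTrials number of trials (default 3).
#' @param durationS trial length in seconds (default 5).
#' @param samplingRate Hz.
#' @param band band edges in Hz.
#' @param meta extra metadata merged into each recording.
#' @return list of \code{nTrials} [EMGRecording-class] objects.
#' @export
generateMVCTrials <- function(layout = gridLayout(), amplitude = 10,
                              seed = 1L, nTrials = 3, durationS = 5,
                              samplingRate = 1000, band = c(10, 500),
                              meta = list()) {
  if (any(amplitude <= 0))
    .configError("MVC amplitude must be strictly positive")
  nch <- nChannels(layout)
  amp <- rep_len(amplitude, nch)
  n <- round(durationS * samplingRate)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  lapply(seq_len(nTrials), function(i) {
    y <- sweep(.bandlimitedNoise(n, nch, samplingRate, band), 2, amp, "*")
    colnames(y) <- channelNames(layout)
    emgRecording(y, samplingRate = samplingRate, layout = layout,
                 meta = utils::modifyList(
                   list(kind = "MVC", mvc_trial = i, seed = as.integer(seed)),
                   meta))
  })
}

## Deterministic per-bundle seed from (study seed, participant, trial index),
## kept inside 32-bit integer range.
.bundleSeed <- function(studySeed, participant, trialIndex) {
  as.integer((as.double(studySeed) * 7919 + participant * 104729 +
                trialIndex * 1299709) %% 2147483629)
}

#' Generate a full synthetic pushing study
#'
#' For every participant, generates the 18 recording trials of the study
#' layout (3 bilateral muscle pairs x 6 handle designs), each bundle holding
#' both sides' grid recordings, the shared force trace, the per-side MVC
#' trial sets of that participant/muscle, and metadata. Per-design
#' ground-truth effects (amplitude gain, spatial clustering) are applied from
#' the design's effect table. Participant heterogeneity is modelled with
#' lognormal amplitude factors; trial-to-trial activation varies
#' lognormally. Every bundle draws from its own RNG stream seeded from
#' (study seed, participant, trial index), so trials are independently
#' reproducible.
#'
#' @param design a [StudyDesign-class].
#' @return an [EMGStudy-class] with
#'   \code{nParticipants * 18} trial bundles.
#' @examples
#' study <- generateStudy(studyDesign(nParticipants = 1, seed = 7))
#' length(study)  # 18
#' @export
generateStudy <- function(design) {
  validObject(design)
  base <- design@baseConfig
  layout <- gridLayout()
  eff <- design@effectTable
  bundles <- vector("list", design@nParticipants * 18L)
  k <- 0L
  for (p in seq_len(design@nParticipants)) {
    pid <- sprintf("P%02d", p)
    sex <- if (p %% 2L == 1L) "F" else "M"
    set.seed(.bundleSeed(design@seed, p, 0L))
    ampFactor <- stats::rlnorm(1, 0, 0.10)   # electrode/skin gain
    actFactor <- stats::rlnorm(1, 0, 0.15)   # behavioral activation level
    ## participant-level MVC sets, one per muscle x side
    mvcSets <- list()
    mi <- 0L
    for (m in design@muscles) for (s in design@sides) {
      mi <- mi + 1L
      mvcSets[[paste(m, s, sep = ".")]] <- generateMVCTrials(
        layout, amplitude = design@mvcAmplitude * ampFactor,
        seed = .bundleSeed(design@seed, p, 100L + mi),
        meta = list(participant = pid, sex = sex, muscle = m, side = s))
    }
    trialIndex <- 0L
    for (d in design@designs) for (m in design@muscles) {
      trialIndex <- trialIndex + 1L
      row <- eff[eff$design == d, ][1, ]
      bseed <- .bundleSeed(design@seed, p, trialIndex)
      set.seed(bseed)
      recs <- list()
      for (s in design@sides) {
        trialFactor <- stats::rlnorm(1, 0, 0.15)
        center <- c((layout@nRows - 1) / 2, (layout@nCols - 1) / 2) +
          stats::runif(2, -0.8, 0.8)
        terr <- sourceTerritory(
          center = pmin(pmax(center, 0), c(layout@nRows, layout@nCols) - 1),
          spread = clusteringToSpread(row$clustering),
          gain = row$gain * ampFactor * actFactor * trialFactor)
        cfg <- simConfig(
          duration = base@duration, samplingRate = base@samplingRate,
          band = base@band, territories = list(terr),
          noiseSd = base@noiseSd * ampFactor, clustering = row$clustering,
          onsetTime = base@onsetTime, forcePlateau = base@forcePlateau,
          seed = bseed)
        recs[[s]] <- generateGridEMG(
          cfg, layout, seed = stats::runif(1, 0, 2^31 - 1),
          meta = list(participant = pid, sex = sex, muscle = m, side = s,
                      design = d))
      }
      force <- generateForceTrace(base, seed = bseed)
      k <- k + 1L
      bundles[[k]] <- list(
        recordings = recs,
        force = force,
        mvc = stats::setNames(
          lapply(design@sides, function(s) mvcSets[[paste(m, s, sep = ".")]]),
          design@sides),
        meta = list(participant = pid, sex = sex, muscle = m, design = d,
                    trial_index = trialIndex, seed = bseed))
    }
  }
  new("EMGStudy", bundles = bundles, design = design)
}
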