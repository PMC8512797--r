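test_that("band-pass rejects stop-band tones and passes in-band tones", {
  fs <- 1000
  t <- (0:1999) / fs
  lay <- fullLayout(2, 1)
  tone <- function(f) sin(2 * pi * f * t)
  rec <- toyRecording(list(tone(5), tone(100)), lay, fs)
  out <- bandpassRecording(rec)
  rmsIn <- sqrt(colMeans(samples(rec)^2))
  rmsOut <- sqrt(colMeans(samples(out)^2))
  expect_lt(rmsOut[1] / rmsIn[1], 0.10)          # 5 Hz: stop band
  expect_lt(abs(rmsOut[2] / rmsIn[2] - 1), 0.05) # 100 Hz: pass band
  expect_identical(nrow(samples(out)), nrow(samples(rec)))

  zero <- bandpassRecording(toyRecording(list(rep(0, 500), rep(0, 500)), lay))
  expect_true(all(samples(zero) == 0))

  expect_error(bandpassRecording(rec, low = 600, high = 700),
               class = "gridEMG_config_error")
})

test_that("band-pass is idempotent up to pass-band ripple for in-band signals", {
  cfg <- simConfig(duration = 2, clustering = 0.4)
  rec <- generateGridEMG(cfg, seed = 12)
  once <- bandpassRecording(rec)
  twice <- bandpassRecording(once)
  r1 <- sqrt(colMeans(samples(once)^2))
  r2 <- sqrt(colMeans(samples(twice)^2))
  expect_true(all(abs(r2 - r1) / r1 < 0.02))
})

test_that("zero-phase Butterworth agrees with signal::filtfilt away from edges", {
  fs <- 1000
  set.seed(99)
  x <- rnorm(3000)
  lay <- fullLayout(1, 1)
  out <- samples(bandpassRecording(toyRecording(list(x), lay, fs)))[, 1]
  ba <- signal::butter(4, c(10, 499) / 500, type = "pass")
  ref <- signal::filtfilt(ba, x)
  core <- 501:2500   # interior samples, away from boundary handling
  relErr <- sqrt(mean((out[core] - ref[core])^2)) / sqrt(mean(ref[core]^2))
  expect_lt(relErr, 0.02)
})

test_that("initiation detection recovers the window after the 20 N crossing", {
  fs <- 1000
  f <- forceTrace(c(rep(0, 1000), rep(30, 2000)), fs)
  w <- detectInitiation(f)
  expect_identical(w@startIndex, 1001L)
  expect_identical(w@endIndex, 1501L)
  expect_identical(w@endIndex - w@startIndex, as.integer(round(0.5 * fs)))

  # adding any sub-threshold baseline leaves the window unchanged
  base <- 15 * abs(sin(2 * pi * (1:3000) / 3000))
  f2 <- forceTrace(c(base[1:1000], rep(30, 2000)), fs)
  expect_identical(detectInitiation(f2)@startIndex, 1001L)

  # offset option: window starting 0.5 s after the crossing
  wOff <- detectInitiation(f, offsetS = 0.5)
  expect_identical(wOff@startIndex, 1501L)

  # minimum-hold option ignores an isolated spike
  spike <- c(rep(0, 500), 25, rep(0, 499), rep(30, 2000))
  wHold <- detectInitiation(forceTrace(spike, fs), minHoldS = 0.05)
  expect_identical(wHold@startIndex, 1001L)
})

test_that("initiation detection raises documented errors", {
  expect_error(detectInitiation(forceTrace(rep(10, 2000))),
               class = "gridEMG_no_initiation")
  late <- c(rep(0, 1950), rep(30, 50))  # crossing 50 ms before the end
  expect_error(detectInitiation(forceTrace(late)),
               class = "gridEMG_truncated_window")
})

test_that("MVC reference is the per-channel max of sliding-window RMS", {
  lay <- fullLayout(2, 2)
  const <- function(a) toyRecording(rep(list(rep(a, 2000)), 4), lay)
  trials <- list(const(1), const(2), const(3))
  ref <- computeMVC(trials)
  expect_equal(unname(mapValues(ref)[!is.na(mapValues(ref))]), rep(3, 4))

  single <- computeMVC(list(const(1.5)))
  expect_equal(unname(mapValues(single)[1, 1]), 1.5)

  # permutation invariance over trials
  ref2 <- computeMVC(trials[c(3, 1, 2)])
  expect_identical(mapValues(ref), mapValues(ref2))

  # an identically zero channel is a degenerate MVC
  zeroCh <- toyRecording(list(rep(0, 2000), rep(1, 2000), rep(1, 2000),
                              rep(1, 2000)), lay)
  expect_error(computeMVC(list(zeroCh, zeroCh)),
               class = "gridEMG_degenerate_mvc")
})

test_that("normalization divides channels by the MVC reference exactly once", {
  lay <- fullLayout(2, 2)
  ref <- computeMVC(list(toyRecording(rep(list(rep(2, 1000)), 4), lay)))
  map <- activationMap(rep(2, 4), lay)
  norm <- normalizeMap(map, ref)
  expect_true(isNormalized(norm))
  expect_equal(unname(mapValues(norm)[!is.na(mapValues(norm))]), rep(1, 4))

  half <- normalizeMap(activationMap(rep(1, 4), lay), ref)
  expect_equal(unname(mapValues(half)[1, 1]), 0.5)

  # scale consistency: normalize(k * map) = k * normalize(map)
  k <- 3.7
  kmap <- activationMap(k * rep(2, 4), lay)
  expect_equal(mapValues(normalizeMap(kmap, ref)),
               k * mapValues(norm))

  expect_error(normalizeMap(norm, ref), class = "gridEMG_config_error")
  otherRef <- computeMVC(list(toyRecording(rep(list(rep(2, 100)), 31),
                                           gridLayout())))
  expect_error(normalizeMap(map, otherRef), class = "gridEMG_config_error")
})
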