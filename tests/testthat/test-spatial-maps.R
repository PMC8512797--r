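test_that("activation maps are per-channel RMS over the window", {
  lay <- fullLayout(2, 1)
  # RMS of a constant is its absolute value
  rec <- toyRecording(list(rep(-3, 1000), rep(2, 1000)), lay)
  m <- buildActivationMap(rec)
  expect_equal(unname(mapValues(m)[, 1]), c(3, 2))

  # sinusoid of amplitude A over whole cycles: RMS = A / sqrt(2)
  t <- (0:999) / 1000
  s <- toyRecording(list(4 * sin(2 * pi * 50 * t), rep(1, 1000)), lay)
  expect_equal(mapValues(buildActivationMap(s))[1, 1], 4 / sqrt(2))

  # direct arithmetic: RMS([3, 4]) = sqrt(12.5)
  two <- toyRecording(list(c(3, 4)), fullLayout(1, 1))
  expect_equal(mapValues(buildActivationMap(two))[1, 1], sqrt(12.5))

  # windows outside the recording are rejected
  expect_error(buildActivationMap(rec, trialWindow(900, 1401)),
               class = "gridEMG_config_error")
})

test_that("intensity is the common log of the mean map amplitude", {
  expect_equal(mapIntensity(activationMap(rep(10, 31))), 1)
  expect_equal(mapIntensity(activationMap(rep(1, 31))), 0)
  expect_equal(mapIntensity(toyMap(c(1, 2, 3, 4))), log10(2.5))
  expect_error(mapIntensity(toyMap(rep(0, 4))),
               class = "gridEMG_undefined_intensity")
})

test_that("intensity obeys the shift rule under global scaling", {
  set.seed(31)
  for (i in 1:10) {
    v <- runif(31, 0.1, 5)
    k <- runif(1, 0.01, 100)
    expect_equal(mapIntensity(activationMap(k * v)),
                 mapIntensity(activationMap(v)) + log10(k))
  }
})

test_that("differential intensity averages fiber-direction pair RMS", {
  # identical signals on every channel: differentials cancel, value floored
  lay <- fullLayout(4, 1)
  x <- sin(2 * pi * 40 * (0:999) / 1000)
  same <- toyRecording(rep(list(x), 4), lay)
  di <- differentialIntensity(same)
  expect_true(attr(di, "floored"))
  expect_equal(as.numeric(di), log10(.Machine$double.eps))

  # a constant offset between a pair gives differential RMS |d|
  pair <- toyRecording(list(x + 2.5, x), fullLayout(2, 1))
  dPair <- differentialIntensity(pair)
  expect_equal(as.numeric(dPair), log10(2.5))
  expect_identical(attr(dPair, "nPairs"), 1L)

  # brute-force oracle on a two-column toy grid
  lay2 <- fullLayout(3, 2)
  chans <- list(c(1, 2), c(3, 5), c(2, 2),    # column 0, rows 0..2
                c(0, 4), c(1, 1), c(7, 3))    # column 1
  rec <- toyRecording(chans, lay2)
  pairs <- list(c(1, 2), c(2, 3), c(4, 5), c(5, 6))
  rmsByHand <- vapply(pairs, function(p) {
    d <- chans[[p[1]]] - chans[[p[2]]]
    sqrt(sum(d^2) / length(d))
  }, numeric(1))
  expect_equal(as.numeric(differentialIntensity(rec)),
               log10(mean(rmsByHand)))
  expect_identical(attr(differentialIntensity(rec), "nPairs"), 4L)
  expect_equal(as.numeric(differentialIntensity(rec,
                                                aggregate = "mean-of-logs")),
               mean(log10(rmsByHand)))

  # the default grid's missing corner breaks one pair: 27 of 28 remain
  full <- generateGridEMG(simConfig(duration = 0.5), seed = 2)
  expect_identical(attr(differentialIntensity(full), "nPairs"), 27L)

  # no adjacent pair along the fiber axis at all
  wide <- toyRecording(list(x, x), fullLayout(1, 2))
  expect_error(differentialIntensity(wide), class = "gridEMG_config_error")
})

test_that("modified entropy matches its closed forms", {
  # 28 equal channels: the log2(28) = 4.8 maximum
  e28 <- modifiedEntropy(activationMap(rep(5, 28), fullLayout(7, 4)))
  expect_equal(e28, log2(28))
  expect_equal(round(e28, 1), 4.8)

  # default 31-electrode grid, uniform map
  expect_equal(modifiedEntropy(activationMap(rep(0.2, 31))), log2(31))

  # single active channel: minimum entropy 0
  expect_equal(modifiedEntropy(toyMap(c(4, 0, 0, 0, 0))), 0)

  # two equal active channels: exactly 1 bit
  expect_equal(modifiedEntropy(toyMap(c(3, 3, 0, 0))), 1)

  expect_error(modifiedEntropy(toyMap(rep(0, 5))),
               class = "gridEMG_undefined_entropy")
})

test_that("entropy stays within [0, log2 N] on random maps", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:31, 1)
    v <- rexp(n) * sample(c(1, 1e-3, 1e3), 1)
    v[sample(n, sample(0:(n - 1), 1))] <- 0
    if (all(v == 0)) v[1] <- 1
    e <- modifiedEntropy(toyMap(v))
    expect_gte(e, 0)
    expect_lte(e, log2(n) + 1e-12)
  }
})

test_that("entropy and CoV are permutation- and scale-invariant", {
  set.seed(13)
  for (i in 1:20) {
    v <- runif(31, 0, 2)
    k <- runif(1, 0.01, 50)
    perm <- sample(v)
    expect_equal(modifiedEntropy(activationMap(perm)),
                 modifiedEntropy(activationMap(v)))
    expect_equal(modifiedEntropy(activationMap(k * v)),
                 modifiedEntropy(activationMap(v)))
    expect_equal(mapCoV(activationMap(perm)), mapCoV(activationMap(v)))
    expect_equal(mapCoV(activationMap(k * v)), mapCoV(activationMap(v)))
  }
})

test_that("CoV uses the sample SD over valid channels, in percent", {
  expect_equal(mapCoV(activationMap(rep(3, 31))), 0)
  # values [1, 3]: sample SD sqrt(2), mean 2 -> 70.71%
  expect_equal(mapCoV(toyMap(c(1, 3))), 100 * sqrt(2) / 2)
  expect_equal(mapCoV(toyMap(c(1, 3)), sdType = "population"), 50)
  expect_error(mapCoV(toyMap(5)), class = "gridEMG_undefined_cov")
  expect_error(mapCoV(toyMap(c(0, 0))), class = "gridEMG_undefined_cov")
})

test_that("mean RMS requires a normalized map and averages valid channels", {
  expect_equal(meanRMS(toyMap(rep(1, 4), normalized = TRUE)), 1)
  expect_equal(meanRMS(toyMap(c(0, 0, 0.2, 0.2), normalized = TRUE)), 0.1)
  expect_equal(meanRMS(toyMap(c(0.06, 0.08, 0.04, 0.06), normalized = TRUE)),
               0.06)
  expect_error(meanRMS(toyMap(rep(1, 4))), class = "gridEMG_config_error")
})

test_that("entropy, CoV and intensity match brute-force oracles to 1e-12", {
  set.seed(2024)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    v <- runif(n, 0.05, 10)
    m <- toyMap(v)
    expect_equal(modifiedEntropy(m), oracleEntropy(v), tolerance = 1e-12)
    expect_equal(mapCoV(m), oracleCoV(v), tolerance = 1e-12)
    expect_equal(mapIntensity(m), oracleIntensity(v), tolerance = 1e-12)
  }
})

test_that("spatialFeatures composes the five features with QC flags", {
  cfg <- simConfig(duration = 2, clustering = 0.6, onsetTime = 1)
  rec <- bandpassRecording(generateGridEMG(cfg, seed = 17))
  win <- detectInitiation(generateForceTrace(cfg))
  mvc <- computeMVC(generateMVCTrials(amplitude = 10, seed = 18))
  f <- spatialFeatures(rec, win, mvc = mvc)
  map <- buildActivationMap(rec, win)
  expect_equal(f@intensity, mapIntensity(map))
  expect_equal(f@entropy, modifiedEntropy(map))
  expect_equal(f@cov, mapCoV(map))
  expect_equal(f@meanRMS, meanRMS(normalizeMap(map, mvc)))
  expect_identical(f@nChannelsUsed, 31L)
  expect_length(f@flags, 0L)
  df <- as.data.frame(f)
  expect_equal(df$mean_rms_pct, 100 * f@meanRMS)
})
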