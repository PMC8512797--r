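test_that("zero-gain, zero-noise configuration produces all-zero channels", {
  cfg <- simConfig(duration = 1, noiseSd = 0,
                   territories = list(sourceTerritory(c(3.5, 1.5), 2, gain = 0)))
  rec <- generateGridEMG(cfg, seed = 5)
  expect_true(all(samples(rec) == 0))
})

test_that("per-channel RMS follows the analytic territory amplitude", {
  # clustering 0: near-uniform weights; noiseless, so channel RMS must sit
  # within 5% of the analytic weight
  cfg <- simConfig(duration = 5, clustering = 0, noiseSd = 0)
  lay <- gridLayout()
  rec <- generateGridEMG(cfg, lay, seed = 42)
  w <- territoryWeights(list(sourceTerritory(
    c(3.5, 1.5), clusteringToSpread(0), 1)), lay)[, 1]
  rms <- sqrt(colMeans(samples(rec)^2))
  expect_true(all(abs(rms - w) / w < 0.05))

  # a tight territory: amplitude profile must follow the weights too
  terr <- sourceTerritory(c(2, 1), spread = 1.2, gain = 2)
  cfg2 <- simConfig(duration = 5, territories = list(terr), noiseSd = 0)
  rec2 <- generateGridEMG(cfg2, lay, seed = 42)
  w2 <- territoryWeights(list(terr), lay)[, 1]
  rms2 <- sqrt(colMeans(samples(rec2)^2))
  expect_lt(max(abs(rms2 - w2)) / max(w2), 0.05)

  # independent noise adds in quadrature
  cfg3 <- simConfig(duration = 5, clustering = 0, noiseSd = 0.5)
  rec3 <- generateGridEMG(cfg3, lay, seed = 42)
  target <- sqrt(w^2 + 0.5^2)
  rms3 <- sqrt(colMeans(samples(rec3)^2))
  expect_true(all(abs(rms3 - target) / target < 0.05))
})

test_that("generation is deterministic given the seed", {
  cfg <- simConfig(duration = 1, clustering = 0.5)
  a <- generateGridEMG(cfg, seed = 7)
  b <- generateGridEMG(cfg, seed = 7)
  expect_identical(samples(a), samples(b))
  c_ <- generateGridEMG(cfg, seed = 8)
  expect_false(identical(samples(a), samples(c_)))
})

test_that("generated EMG power outside the 10-500 Hz band is below 1%", {
  cfg <- simConfig(duration = 4, clustering = 0.3, noiseSd = 0.1)
  rec <- generateGridEMG(cfg, seed = 3)
  x <- samples(rec)[, 1]
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * samplingRate(rec) / n
  half <- freq <= samplingRate(rec) / 2
  inBand <- half & freq >= 10 & freq <= 500
  expect_lt(sum(p[half & !inBand]) / sum(p[half]), 0.01)
})

test_that("force trace crosses the threshold at the configured onset", {
  fs <- 1000
  cfg <- simConfig(duration = 3, onsetTime = 1, forcePlateau = 100)
  f <- forceValues(generateForceTrace(cfg))
  firstAbove <- which(f > 20)[1]
  expect_lte(abs(firstAbove - (1 * fs + 1L)), 1L)   # onset +/- one sample
  expect_true(all(f[seq_len(1 * fs)] <= 20))        # below threshold pre-onset
  expect_equal(max(f), 100)
  expect_true(all(diff(f) >= 0))                    # monotone rise

  # a 10 N plateau never reaches the threshold
  low <- generateForceTrace(simConfig(duration = 3, onsetTime = 1,
                                      forcePlateau = 10))
  expect_true(all(forceValues(low) < 20))

  # with measurement noise, pre-onset samples stay below threshold
  noisy <- generateForceTrace(cfg, seed = 9, noiseSdN = 1)
  expect_true(all(forceValues(noisy)[seq_len(fs)] < 20))

  expect_error(generateForceTrace(simConfig(duration = 1.2, onsetTime = 1)),
               class = "gridEMG_config_error")
})

test_that("MVC trials are three five-second recordings centered on the amplitude", {
  lay <- gridLayout()
  trials <- generateMVCTrials(lay, amplitude = 1, seed = 4)
  expect_length(trials, 3L)
  for (tr in trials) {
    expect_equal(nrow(samples(tr)) / samplingRate(tr), 5)
    expect_equal(sqrt(colMeans(samples(tr)^2)), rep(1, 31),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(generateMVCTrials(lay, amplitude = 0),
               class = "gridEMG_config_error")
  a <- generateMVCTrials(lay, amplitude = 2, seed = 1)
  b <- generateMVCTrials(lay, amplitude = 2, seed = 1)
  d <- generateMVCTrials(lay, amplitude = 2, seed = 2)
  expect_identical(samples(a[[1]]), samples(b[[1]]))
  expect_false(identical(samples(a[[1]]), samples(d[[1]])))
})

test_that("a study has 18 bundles per participant with per-design effects applied", {
  des <- studyDesign(nParticipants = 1, seed = 21,
                     baseConfig = simConfig(duration = 1.6, onsetTime = 1))
  study <- generateStudy(des)
  expect_identical(length(study), 18L)
  metas <- lapply(study@bundles, `[[`, "meta")
  combos <- unique(paste(vapply(metas, `[[`, "", "muscle"),
                         vapply(metas, `[[`, "", "design")))
  expect_length(combos, 18L)   # every muscle x design exactly once
  b <- study[[1]]
  expect_named(b$recordings, c("left", "right"))
  expect_length(b$mvc$left, 3L)
  # identical seed regenerates the identical study
  again <- generateStudy(des)
  expect_identical(samples(study[[5]]$recordings$left),
                   samples(again[[5]]$recordings$left))
})

test_that("an identity effect table makes designs exchangeable by construction", {
  eff <- defaultEffectTable()
  eff$gain <- 1
  eff$clustering <- 0.5
  des <- studyDesign(nParticipants = 1, effectTable = eff, seed = 3,
                     baseConfig = simConfig(duration = 1.6, onsetTime = 1))
  study <- generateStudy(des)
  gt <- vapply(study@bundles, function(b)
    metaData(b$recordings$left)$ground_truth$clustering, numeric(1))
  expect_true(all(gt == 0.5))
})

test_that("median entropy falls and CoV rises monotonically with clustering", {
  levels <- c(0, 0.5, 0.75, 0.9, 1)
  seeds <- 1:20
  ent <- cov <- matrix(NA_real_, length(seeds), length(levels))
  for (j in seq_along(levels)) {
    for (i in seq_along(seeds)) {
      cfg <- simConfig(duration = 1, clustering = levels[j])
      map <- buildActivationMap(generateGridEMG(cfg, seed = seeds[i]))
      ent[i, j] <- modifiedEntropy(map)
      cov[i, j] <- mapCoV(map)
    }
  }
  medE <- apply(ent, 2, median)
  medC <- apply(cov, 2, median)
  expect_true(all(diff(medE) < 0))
  expect_true(all(diff(medC) > 0))
  expect_lte(cor(medE, levels, method = "spearman"), -0.9)
  expect_gte(cor(medC, levels, method = "spearman"), 0.9)
})
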