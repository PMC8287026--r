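rawWave <- function(t, y) thicknessWaveform(t, y)

test_that("MAD outlier removal follows the 3-scaled-MAD rule", {
  w <- rawWave(0:5, c(10, 10, 11, 9, 10, 50))
  cl <- removeOutliersMAD(w)
  expect_equal(chtSeries(cl), c(10, 10, 11, 9, 10))
  expect_equal(scanTimes(cl), 0:4)

  const <- removeOutliersMAD(rawWave(0:5, rep(7, 6)))
  expect_equal(chtSeries(const), rep(7, 6))    # zero-MAD guard

  tame <- removeOutliersMAD(rawWave(0:5, c(10, 11, 9, 10.5, 9.5, 10)))
  expect_equal(chtSeries(tame), c(10, 11, 9, 10.5, 9.5, 10))

  expect_error(removeOutliersMAD(rawWave(0:2, c(1, 2, 3))), "5 points")
})

test_that("uniform resampling is near-identity and preserves amplitude", {
  t <- seq(0, 6, by = 1 / 50)
  y <- 300 + 5 * sin(2 * pi * 1.2 * t)
  u <- resampleUniform(rawWave(t, y), targetRateHz = 50)
  expect_equal(u@sampleRate, 50)
  expect_lt(max(abs(chtSeries(u) - approx(t, y, scanTimes(u))$y)) / 10,
            0.01)                             # within 1% of peak-to-peak

  # irregular sampling with 20% jitter: amplitude recovered within 2%
  set.seed(3)
  ti <- seq(0, 6, by = 0.04)
  ti <- sort(ti + runif(length(ti), -0.008, 0.008))
  yi <- 5 * sin(2 * pi * 1.2 * ti)
  u2 <- resampleUniform(rawWave(ti, yi), targetRateHz = 50)
  amp <- toneAmplitude(scanTimes(u2), chtSeries(u2), 1.2)
  expect_equal(amp, 5, tolerance = 0.02)

  # zero net delay: a Gaussian bump's peak time is preserved
  tb <- seq(0, 4, by = 0.02)
  yb <- exp(-(tb - 1.7)^2 / (2 * 0.15^2))
  u3 <- resampleUniform(rawWave(tb, yb), targetRateHz = 50)
  expect_lt(abs(scanTimes(u3)[which.max(chtSeries(u3))] - 1.7),
            1 / 50 + 1e-9)

  expect_error(resampleUniform(rawWave(t, y), targetRateHz = 10),
               "Nyquist")
})

test_that("spectral heart-rate estimate finds the cardiac peak", {
  t <- seq(0, 6, by = 1 / 50)
  u <- resampleUniform(rawWave(t, 300 + 4 * sin(2 * pi * 1.2 * t)),
                       targetRateHz = 50)
  expect_equal(estimateHeartRate(u), 1.2, tolerance = 0.05)

  # linear drift must not disturb the estimate (detrending)
  u2 <- resampleUniform(rawWave(t, 300 + 20 * t + 4 * sin(2 * pi * 1.2 * t)),
                        targetRateHz = 50)
  expect_equal(estimateHeartRate(u2), 1.2, tolerance = 0.05)

  set.seed(1)
  u3 <- resampleUniform(rawWave(t, rnorm(length(t))), targetRateHz = 50)
  expect_error(estimateHeartRate(u3), "explicitly")

  short <- resampleUniform(rawWave(seq(0, 1, by = 0.02),
                                   sin(2 * pi * 1.2 * seq(0, 1, by = 0.02))),
                           targetRateHz = 50)
  expect_error(estimateHeartRate(short), "two cycles")
})

test_that("band-pass: pass-band identity, stop-band annihilation, linearity", {
  fs <- 80
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)     # 5 s: bin-aligned tones at k/5 Hz
  inband <- 5 * sin(2 * pi * 1.2 * t)
  lowTone <- 20 * sin(2 * pi * 0.2 * t)
  highTone <- 3 * sin(2 * pi * 30 * t)
  mk <- function(y) {
    w <- thicknessWaveform(t, y, stage = "uniform", sampleRate = fs)
    w
  }
  f <- bandpassFilter(mk(inband + lowTone + highTone), 1.2)
  y <- chtSeries(f)
  expect_lt(abs(mean(y)), 0.01 * sd(y))
  expect_equal(toneAmplitude(t, y, 1.2), 5, tolerance = 0.02)
  expect_lt(toneAmplitude(t, y, 0.2), 0.05)     # >= 40 dB down
  expect_lt(toneAmplitude(t, y, 30), 0.05)

  # in-band input is passed through
  fIn <- bandpassFilter(mk(inband), 1.2)
  expect_equal(chtSeries(fIn), inband, tolerance = 0.02)

  # out-of-band input is annihilated
  fOut <- bandpassFilter(mk(lowTone + highTone), 1.2)
  expect_lt(sqrt(mean(chtSeries(fOut)^2)) /
              sqrt(mean((lowTone + highTone)^2)), 0.01)

  # linearity
  y1 <- rnorm(length(t)); y2 <- rnorm(length(t))
  b1 <- chtSeries(bandpassFilter(mk(y1), 1.2))
  b2 <- chtSeries(bandpassFilter(mk(y2), 1.2))
  b12 <- chtSeries(bandpassFilter(mk(y1 + 2 * y2), 1.2))
  expect_equal(b12, b1 + 2 * b2, tolerance = 1e-8)

  expect_error(bandpassFilter(mk(inband), 20), "Nyquist")
})

test_that("mean peak-to-valley amplitude of oscillatory signals", {
  t <- seq(0, 6, by = 0.02)
  expect_equal(meanPeakToValley(5 * sin(2 * pi * 1.2 * t)), 10,
               tolerance = 0.02)

  # amplitude-modulated cycles with peak-to-valleys 8, 10, 12
  tm <- seq(0, 3 - 0.01, by = 0.01)
  amp <- c(4, 5, 6)[pmin(floor(tm), 2) + 1]
  ym <- amp * sin(2 * pi * tm)
  expect_equal(meanPeakToValley(ym, minProminenceUm = 1), 10,
               tolerance = 0.02)

  expect_error(meanPeakToValley(rep(1, 100)), "no peak")
})

test_that("extractDeltaT recovers the simulated pulse", {
  sim <- simulateBScans(tinySimParams(nFrames = 150, durationS = 5,
                                      widthPx = 120,
                                      driftAmplitudeUm = 2,
                                      pauseProb = 0.01, seed = 4))
  raw <- segmentSequence(scanSequence(sim))
  tr <- groundTruth(sim)
  w <- extractDeltaT(raw)
  expect_gte(deltaT(w), 0.95 * tr@trueDeltaTUm - 0.5)
  expect_lte(deltaT(w), 1.05 * tr@trueDeltaTUm + 0.5)
  expect_length(w@history, 3)                 # raw, cleaned, uniform

  # supplying the generator heart rate barely changes the result
  w2 <- extractDeltaT(raw, heartRateHz = 1.2)
  expect_equal(deltaT(w2), deltaT(w), tolerance = 0.02)
})

test_that("waveform pipeline invariances: time shift and amplitude scale", {
  set.seed(8)
  t <- sort(runif(240, 0, 6))
  y <- 310 + 5 * sin(2 * pi * 1.1 * t) + rnorm(240, 0, 0.4)
  w1 <- extractDeltaT(rawWave(t, y))
  w2 <- extractDeltaT(rawWave(t + 37.5, y))
  expect_equal(w2@heartRate, w1@heartRate)
  expect_equal(deltaT(w2), deltaT(w1), tolerance = 1e-9)

  w3 <- extractDeltaT(rawWave(t, 3 * y))
  expect_equal(deltaT(w3), 3 * deltaT(w1), tolerance = 1e-9)
})

test_that("stage errors carry the failing stage's name", {
  expect_error(extractDeltaT(rawWave(0:3, c(1, 2, 1, 2))),
               "\\[outlier-removal\\]")
  set.seed(2)
  t <- seq(0, 6, by = 0.02)
  expect_error(extractDeltaT(rawWave(t, rnorm(length(t)))),
               "\\[heart-rate\\]")
})
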