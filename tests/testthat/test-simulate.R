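test_that("timestamps: uniform spacing without pauses, monotone with", {
  t <- simulateTimestamps(599, 4, pauseProb = 0)
  expect_equal(length(t), 599)
  expect_equal(unique(round(diff(t), 10)), 4 / 598)
  expect_equal(t[1], 0)

  for (seed in 1:5) {
    tp <- simulateTimestamps(200, 4, pauseProb = 0.05, pauseLenS = 0.5,
                             seed = seed)
    expect_true(all(diff(tp) > 0))
    expect_gte(max(tp), 4)
  }
  expect_error(simulateTimestamps(1, 4), "nFrames")
})

test_that("B-scan simulator: seeded determinism and noise-free truths", {
  p <- tinySimParams(nFrames = 6, pulseAmplitudeUm = 5, seed = 7)
  a <- simulateBScans(p)
  b <- simulateBScans(p)
  expect_identical(scanSequence(a)@frames, scanSequence(b)@frames)
  expect_identical(groundTruth(a)@chtUm, groundTruth(b)@chtUm)

  # noise-free sinusoid: peak-to-valley is exactly 2A
  sim <- simulateBScans(tinySimParams(nFrames = 60, durationS = 4,
                                      pulseAmplitudeUm = 5))
  expect_equal(groundTruth(sim)@trueDeltaTUm, 10, tolerance = 1e-3)

  # no dynamics: constant thickness at baseline
  flat <- simulateBScans(tinySimParams(nFrames = 10, pulseAmplitudeUm = 0))
  expect_equal(groundTruth(flat)@chtUm, rep(300, 10))
  expect_equal(groundTruth(flat)@trueDeltaTUm, 0)

  expect_error(simulateBScans(tinySimParams(nFrames = 1)), "nFrames")
  expect_error(bscanSimParams(axialSpacingUm = 0), "axialSpacingUm")
})

test_that("simulated frames have the expected layer structure", {
  sim <- simulateBScans(tinySimParams(nFrames = 3, tiltPxPerAscan = 0,
                                      vesselAmplitude = 0))
  s <- scanSequence(sim)
  tr <- groundTruth(sim)
  f <- frameData(s, 1)
  j <- 5                                   # an included column
  rpe0 <- tr@rpeDepthPx[1, j]
  csi0 <- tr@csiDepthPx[1, j]
  expect_lt(f[10, j], 0.2)                 # vitreous dark
  expect_gt(f[rpe0 + 1, j], 0.85)          # bright RPE at its 0-based depth
  expect_lt(f[floor(csi0) - 2 + 1, j], 0.35)   # choroid mid-dark
  expect_gt(f[ceiling(csi0) + 2 + 1, j], 0.45) # sclera brighter: dark->bright
  # optic-nerve band has no bright RPE
  onr <- onRegion(s)
  gapCol <- f[, onr[1] + 1]
  expect_lt(max(gapCol), 0.5)
})

test_that("cohort simulator: correlation structure is honoured", {
  m <- diag(6)
  vars <- c("k", "al", "acv", "opa", "sp_a1", "sp_hc")
  dimnames(m) <- list(vars, vars)
  m["k", "al"] <- m["al", "k"] <- -0.5
  co <- simulateCohort(cohortSimParams(nSubjects = 2000,
                                       targetCorrelations = m, seed = 11))
  expect_equal(cor(co$k_true_per_ul, co$al_mm), -0.5, tolerance = 0.05)

  ident <- simulateCohort(cohortSimParams(nSubjects = 1000,
                                          targetCorrelations = diag(6) +
                                            0 * m, seed = 3))
  offdiag <- cor(ident[, c("k_true_per_ul", "al_mm", "acv_ul",
                           "opa_mmhg")])
  expect_lt(max(abs(offdiag[upper.tri(offdiag)])), 0.1)
})

test_that("cohort simulator: degenerate and invalid inputs", {
  empty <- simulateCohort(cohortSimParams(nSubjects = 0))
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0)

  bad <- diag(6)
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- 0.9
  bad[1, 3] <- bad[3, 1] <- -0.9           # not positive semidefinite
  vars <- c("k", "al", "acv", "opa", "sp_a1", "sp_hc")
  dimnames(bad) <- list(vars, vars)
  expect_error(cohortSimParams(targetCorrelations = bad),
               "semidefinite")
  expect_error(cohortSimParams(targetCorrelations = matrix(1, 2, 3)),
               "square")
})

test_that("cohort OPA back-computation satisfies Friedenwald exactly", {
  co <- simulateCohort(cohortSimParams(nSubjects = 50, seed = 5))
  dv <- pi * co$al_mm^2 * co$delta_t_um / 1000
  kHat <- log1p(co$opa_mmhg / co$iop_mmhg) / dv
  expect_equal(kHat, co$k_true_per_ul, tolerance = 1e-9)
})

test_that("ground-truth consistency: segmentation recovers the simulated ChT", {
  sim <- simulateBScans(tinySimParams(nFrames = 12, tiltPxPerAscan = 0.05))
  res <- segmentSequence(scanSequence(sim), details = TRUE)
  tr <- groundTruth(sim)
  errPx <- abs(chtSeries(res$segmentation) - tr@chtUm) /
    axialSpacing(scanSequence(sim))
  expect_true(all(errPx <= 1))
})
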