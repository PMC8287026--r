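test_that("detectRPE finds the posterior edge of a bright band", {
  f <- matrix(0.1, 120, 40)
  f[49:53, ] <- 0.9                       # 0-based depths 48..52
  expect_equal(unname(detectRPE(f)), rep(52, 40))

  expect_error(detectRPE(matrix(0.5, 80, 30)),
               class = "ocupulseUnusableFrame")
})

test_that("detectRPE recovers a tilted profile", {
  sim <- simulateBScans(tinySimParams(nFrames = 2, tiltPxPerAscan = 0.05))
  s <- scanSequence(sim)
  prof <- detectRPE(frameData(s, 1), onRegion(s))
  inc <- !(seq_along(prof) - 1 >= onRegion(s)[1] &
             seq_along(prof) - 1 < onRegion(s)[2])
  slope <- coef(lm(prof[inc] ~ which(inc)))[2]
  expect_equal(unname(slope), 0.05, tolerance = 0.1)
})

test_that("flattening brings the RPE onto a common row and inverts", {
  sim <- simulateBScans(tinySimParams(nFrames = 2, tiltPxPerAscan = 0.08))
  s <- scanSequence(sim)
  f <- frameData(s, 1)
  rpe <- detectRPE(f, onRegion(s))
  flat <- flattenFrame(f, rpe, onRegion(s))
  rpeFlat <- detectRPE(flat$frame, onRegion(s))
  cols0 <- seq_along(rpe) - 1
  left <- cols0 < onRegion(s)[1]
  right <- cols0 >= onRegion(s)[2]
  expect_lte(var(rpeFlat[left]), 1)      # each side has its own reference
  expect_lte(var(rpeFlat[right]), 1)

  # already-flat frame: identity transform
  f2 <- matrix(0.1, 100, 30)
  f2[41:45, ] <- 0.9
  flat2 <- flattenFrame(f2, detectRPE(f2), c(0L, 0L))
  expect_true(all(flat2$shiftPx == 0))
  expect_identical(flat2$frame, f2)

  # round-trip up to padded rows
  un <- unflattenFrame(flat)
  pad <- max(abs(flat$shiftPx))
  interior <- (pad + 1):(nrow(f) - pad)
  expect_equal(un[interior, ], f[interior, ])

  expect_error(flattenFrame(f2, c(rep(0, 15), rep(250, 15)), c(0L, 0L)),
               "shift")
})

test_that("inflection nodes mark dark-to-bright transitions only", {
  x <- seq_len(300) - 1
  prof <- 80 + 80 / (1 + exp(-(x - 140) / 2))
  nd <- findInflectionNodes(prof, rpeDepthPx = 100, smoothingSigma = 2)
  expect_equal(nrow(nd), 1)
  expect_lte(abs(nd$depth - 140), 1)

  # monotonically decreasing: no dark->bright candidates
  nd2 <- findInflectionNodes(rev(prof), rpeDepthPx = 10)
  expect_equal(nrow(nd2), 0)

  # two steps: both found, gradients ordered by step height
  prof3 <- 60 + 30 / (1 + exp(-(x - 120) / 2)) +
    90 / (1 + exp(-(x - 160) / 2))
  nd3 <- findInflectionNodes(prof3, rpeDepthPx = 80)
  expect_equal(nrow(nd3), 2)
  expect_equal(nd3$depth, c(120, 160), tolerance = 1)
  expect_lt(nd3$grad[1], nd3$grad[2])

  expect_error(findInflectionNodes(c(1, 2, 3), 0), "short")
})

test_that("graph search follows the strong boundary", {
  mk <- function(depths, grads)
    Map(function(d, g) list(depth = d, grad = g), depths, grads)
  # unique candidate per column
  n1 <- mk(rep(140, 5), rep(1, 5))
  p1 <- graphSearchCSI(n1, 15)
  expect_equal(p1$depthPx, rep(140, 5))

  # weak decoy at 100 vs strong edge at 140
  n2 <- lapply(1:5, function(j) list(depth = c(100, 140),
                                     grad = c(0.3, 1.5)))
  p2 <- graphSearchCSI(n2, 15)
  expect_equal(p2$depthPx, rep(140, 5))

  # an outlier displaced beyond the jump limit is bridged over
  n3 <- mk(c(140, 140, 200, 140, 140), rep(1, 5))
  p3 <- graphSearchCSI(n3, 15)
  expect_equal(p3$depthPx, rep(140, 5))
  expect_false(p3$chosen[3])

  expect_error(graphSearchCSI(mk(140, 1), 15),
               class = "ocupulseUnusableFrame")
})

test_that("graph search equals exhaustive enumeration on toy instances", {
  set.seed(42)
  for (i in 1:60) {
    nodes <- randomGraphInstance()
    got <- graphSearchCSI(nodes, 15)$cost
    want <- enumeratePathCost(nodes, 15)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("choroidal thickness arithmetic and exclusion semantics", {
  expect_equal(choroidalThickness(rep(150, 10), rep(50, 10), 3.87), 387)
  expect_equal(choroidalThickness(rep(70, 4), rep(70, 4), 3.87), 0)

  csi <- c(rep(150, 5), rep(999, 5))       # junk in the excluded half
  rpe <- rep(50, 10)
  inc <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(choroidalThickness(csi, rpe, 3.87, include = inc),
               choroidalThickness(csi[1:5], rpe[1:5], 3.87))
  expect_true(is.na(choroidalThickness(NA_real_, 1, 3.87)))
})

test_that("segmentSequence: recovery, drop semantics, ordering", {
  sim <- simulateBScans(tinySimParams(nFrames = 12))
  s <- scanSequence(sim)
  res <- segmentSequence(s, details = TRUE)
  tr <- groundTruth(sim)
  errPx <- abs(chtSeries(res$segmentation) - tr@chtUm) / axialSpacing(s)
  expect_true(all(errPx <= 1))
  expect_true(all(diff(scanTimes(res$waveform)) > 0))

  # corrupt two frames to structureless noise: dropped, rest intact
  set.seed(1)
  s2 <- s
  for (i in c(4, 9))
    s2@frames[[i]] <- matrix(runif(200 * 100), 200, 100)
  res2 <- segmentSequence(s2, details = TRUE)
  expect_false(any(res2$segmentation@usable[c(4, 9)]))
  expect_equal(sum(res2$segmentation@usable), 10)
  keep <- res2$segmentation@usable
  expect_equal(chtSeries(res2$segmentation)[keep],
               chtSeries(res$segmentation)[keep])

  # fewer than 2 usable frames: pipeline error
  s3 <- s2
  for (i in seq_len(12)) s3@frames[[i]] <- matrix(runif(200 * 100), 200, 100)
  expect_error(segmentSequence(s3), "usable")
})

test_that("a constant choroid yields a near-constant waveform", {
  sim <- simulateBScans(tinySimParams(nFrames = 15, pulseAmplitudeUm = 0,
                                      speckleSigma = 0.3, seed = 6))
  res <- segmentSequence(scanSequence(sim))
  # residual ChT fluctuation stays below one axial pixel of speckle noise
  expect_lte(sd(chtSeries(res)), axialSpacing(scanSequence(sim)))
})

test_that("CSI path is invariant to intensity offset and ON-region content", {
  sim <- simulateBScans(tinySimParams(nFrames = 2, speckleSigma = 0.15))
  s <- scanSequence(sim)
  f <- frameData(s, 1)
  base <- segmentFrame(f, onRegion(s), axialSpacing(s))

  off <- segmentFrame(f + 0.2, onRegion(s), axialSpacing(s))
  expect_equal(off$csiDepthPx, base$csiDepthPx)
  expect_equal(off$chtUm, base$chtUm)

  g <- f
  cols <- (onRegion(s)[1] + 1):onRegion(s)[2]     # 1-based inside [lo, hi)
  g[, cols] <- matrix(runif(nrow(g) * length(cols)), nrow(g))
  scrambled <- segmentFrame(g, onRegion(s), axialSpacing(s))
  expect_equal(scrambled$csiDepthPx, base$csiDepthPx)
  expect_equal(scrambled$chtUm, base$chtUm)
})
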