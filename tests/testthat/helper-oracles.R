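# Independent oracles and small fixture builders used across the suite.

# Small, fast simulation defaults for unit tests.
tinySimParams <- function(...) {
  args <- list(nFrames = 20L, durationS = 2, widthPx = 100L,
               depthPx = 200L, speckleSigma = 0, driftAmplitudeUm = 0,
               pauseProb = 0, seed = 1)
  args[names(list(...))] <- list(...)
  do.call(bscanSimParams, args)
}

# Exhaustive enumeration of all one-node-per-column paths under the jump
# constraint, with the normalized-gradient node cost recomputed here from
# its definition. Returns the minimum total cost (Inf if infeasible).
enumeratePathCost <- function(nodes, maxJumpPx) {
  sizes <- vapply(nodes, function(x) length(x$depth), integer(1))
  stopifnot(all(sizes > 0))
  g <- unlist(lapply(nodes, `[[`, "grad"))
  gn <- if (max(g) > min(g)) (g - min(g)) / (max(g) - min(g))
        else rep(1, length(g))
  costs <- split(2 - gn + 1e-6, rep(seq_along(nodes), sizes))
  combos <- expand.grid(lapply(sizes, seq_len))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    pick <- as.integer(combos[r, ])
    depths <- mapply(function(n, k) n$depth[k], nodes, pick)
    if (length(depths) > 1 && any(abs(diff(depths)) > maxJumpPx)) next
    tot <- sum(mapply(function(cc, k) cc[k], costs, pick))
    best <- min(best, tot)
  }
  best
}

# Random graph-search toy instance that always contains a feasible
# backbone path, plus decoy nodes that may or may not be reachable.
randomGraphInstance <- function(ncol = sample(2:6, 1),
                                maxNodes = 4, maxJumpPx = 15) {
  backbone <- cumsum(c(sample(40:60, 1),
                       sample(-maxJumpPx:maxJumpPx, ncol - 1,
                              replace = TRUE)))
  nodes <- lapply(seq_len(ncol), function(j) {
    extra <- sample(0:(maxNodes - 1), 1)
    depth <- c(backbone[j],
               sample(setdiff(1:120, backbone[j]), extra))
    list(depth = as.numeric(depth), grad = stats::runif(extra + 1, 0.1, 2))
  })
  nodes
}

# Exhaustive two-sided permutation p-value for the rank-sum statistic.
permutationMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  uStat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- uStat(seq_len(n1))
  us <- apply(combos, 2, uStat)
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Independent paraxial oracle: chains the single-surface/thin-lens image
# equations with explicit object and image distances (metres) instead of
# reduced-vergence arithmetic.
oracleAxialLength <- function(seD, radiusMm, eye = schematicEyeConstants()) {
  n2 <- eye$nAqueous
  fc <- (n2 - 1) / (radiusMm / 1000)
  vergIn <- seD                       # far-point vergence at the cornea
  # cornea: n2/v - 1/u = Fc with 1/u = vergIn
  v1 <- n2 / (fc + vergIn)
  u2 <- v1 - eye$corneaLensSepMm / 1000
  v2 <- n2 / (eye$lensPowerD + n2 / u2)
  raw <- eye$corneaLensSepMm + v2 * 1000
  raw0 <- {
    v1e <- n2 / ((n2 - 1) / (eye$referenceRadiusMm / 1000))
    u2e <- v1e - eye$corneaLensSepMm / 1000
    v2e <- n2 / (eye$lensPowerD + n2 / u2e)
    eye$corneaLensSepMm + v2e * 1000
  }
  raw + (eye$emmetropicAlMm - raw0)
}

# Least-squares amplitude of a tone at frequency f in series (t, y).
toneAmplitude <- function(t, y, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- stats::coef(stats::lm(y ~ X - 1))
  sqrt(sum(cf^2))
}
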