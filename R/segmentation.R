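# CSI segmentation: RPE detection, flattening, inflection-node extraction,
# and a minimum-cost graph search for the choroidal-scleral interface.
#
# Coordinates: depths are 0-based pixels (row index - 1), columns are
# 0-based A-scan indices, and the optic-nerve exclusion interval is
# half-open [lo, hi).

.unusable <- function(msg) {
  stop(errorCondition(msg, class = c("ocupulseUnusableFrame", "error")))
}

#' Segmentation tuning parameters
#'
#' @param smoothingSigma Gaussian smoothing sigma (pixels, along depth)
#'   applied before inflection-point detection. Raw second differences on
#'   speckle are sign-unstable, so some axial smoothing is required.
#' @param maxJumpPx maximum CSI depth change (pixels) between adjacent
#'   A-scans; transitions beyond this are forbidden in the graph.
#' @param rpeMedianWindow window (columns) of the median filter applied to
#'   the per-A-scan RPE posterior-edge profile.
#' @param rpeBandFrac a pixel belongs to the RPE band while its intensity
#'   stays within this fraction of the band peak (measured above the
#'   column floor, so detection is offset-invariant).
#' @param rpeAxialWindow axial moving-average window (pixels) used before
#'   the band search.
#' @param lateralWindow moving-average window (columns) applied across
#'   A-scans before band and node detection to suppress speckle; the
#'   retinal surfaces are locally near-flat, so a few columns of lateral
#'   averaging blur the boundaries negligibly.
#' @param maxEdgeCoherencePx frame-usability guard: the median absolute
#'   column-to-column change of the detected RPE edge must not exceed this
#'   (a structureless frame yields an incoherent edge profile).
#' @param minUsableColFrac minimum fraction of included columns with a
#'   detectable bright band.
#' @return A named list of class `segmentationControl`.
#' @export
segmentationControl <- function(smoothingSigma = 2, maxJumpPx = 15,
                                rpeMedianWindow = 15, rpeBandFrac = 0.7,
                                rpeAxialWindow = 5, lateralWindow = 7,
                                maxEdgeCoherencePx = 8,
                                minUsableColFrac = 0.5) {
  stopifnot(smoothingSigma > 0, maxJumpPx > 0, rpeMedianWindow >= 1,
            rpeBandFrac > 0, rpeBandFrac < 1, minUsableColFrac > 0,
            lateralWindow >= 1)
  structure(list(smoothingSigma = smoothingSigma, maxJumpPx = maxJumpPx,
                 rpeMedianWindow = rpeMedianWindow,
                 rpeBandFrac = rpeBandFrac, rpeAxialWindow = rpeAxialWindow,
                 lateralWindow = lateralWindow,
                 maxEdgeCoherencePx = maxEdgeCoherencePx,
                 minUsableColFrac = minUsableColFrac),
            class = c("segmentationControl", "list"))
}

# column-wise convolution with a centred kernel, edge replication;
# implemented as shifted-matrix sums (much faster than stats::filter's
# ts dispatch for small kernels)
.convCols <- function(m, kern) {
  h <- (length(kern) - 1L) %/% 2L
  n <- nrow(m)
  padded <- rbind(m[rep(1L, h), , drop = FALSE], m,
                  m[rep(n, h), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kern))
    out <- out + kern[k] * padded[k:(k + n - 1L), , drop = FALSE]
  out
}

# moving-average smoothing of each column with edge replication
.axialSmooth <- function(m, k) {
  if (k <= 1) return(m)
  k <- as.integer(k); if (k %% 2L == 0L) k <- k + 1L
  .convCols(m, rep(1 / k, k))
}

# Gaussian smoothing of each column with edge replication
.gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-h, h), sd = sigma)
  .convCols(m, kern / sum(kern))
}

# carry the last nonzero sign forward through runs of exact zeros, so a
# second derivative that touches zero at a symmetric inflection still
# produces one crossing
.carrySign <- function(v) {
  s <- sign(v)
  nz <- s != 0
  if (!any(nz)) return(s)
  idx <- cumsum(nz)
  first <- which(nz)[1]
  out <- s
  pos <- idx > 0
  out[pos] <- s[nz][idx[pos]]
  out[!pos] <- s[first]
  out
}

# Vectorized inflection-node extraction over a whole smoothed frame:
# returns per-column lists with fields depth (0-based) and grad, keeping
# only rising-edge candidates (second derivative crossing + -> -, i.e.
# the centre of a dark->bright transition) strictly below minDepth[j].
.frameNodes <- function(sm, cols, minDepth) {
  n <- nrow(sm)
  d1 <- (sm[3:n, , drop = FALSE] - sm[1:(n - 2), , drop = FALSE]) / 2
  d2 <- sm[3:n, , drop = FALSE] - 2 * sm[2:(n - 1), , drop = FALSE] +
    sm[1:(n - 2), , drop = FALSE]
  s <- matrix(apply(d2, 2, .carrySign), nrow(d2), ncol(d2))
  sc <- s[-nrow(s), , drop = FALSE] > 0 & s[-1, , drop = FALSE] < 0
  idx <- which(sc, arr.ind = TRUE)
  out <- stats::setNames(rep(list(list(depth = numeric(0),
                                       grad = numeric(0))), length(cols)),
                         as.character(cols))
  if (!nrow(idx)) return(out)
  a <- abs(d1[idx])
  b <- abs(d1[cbind(idx[, 1] + 1L, idx[, 2])])
  row <- idx[, 1] + as.integer(b > a)      # d1/d2 row r = depth0 r
  grad <- d1[cbind(row, idx[, 2])]
  depth0 <- row
  floorG <- 1e-7 * diff(range(sm))         # reject float-noise inflections
  keep <- !is.na(grad) & grad > floorG & idx[, 2] %in% cols &
    depth0 > minDepth[idx[, 2]] + 1
  if (!any(keep)) return(out)
  depth0 <- depth0[keep]; grad <- grad[keep]; col <- idx[keep, 2]
  o <- order(col, depth0)
  depth0 <- depth0[o]; grad <- grad[o]; col <- col[o]
  dup <- duplicated(paste(col, depth0))
  depth0 <- depth0[!dup]; grad <- grad[!dup]; col <- col[!dup]
  for (j in unique(col)) {
    sel <- col == j
    out[[as.character(j)]] <- list(depth = depth0[sel], grad = grad[sel])
  }
  out
}

# moving-average smoothing across columns, applied per contiguous run of
# included columns (never across the optic-nerve gap, so results stay
# invariant to the excluded region's content); excluded columns untouched
.lateralSmooth <- function(m, k, inc) {
  if (k <= 1) return(m)
  k <- as.integer(k); if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  runs <- rle(inc)
  pos <- cumsum(c(1L, runs$lengths))
  out <- m
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    idx <- pos[r]:(pos[r + 1L] - 1L)
    if (length(idx) < 2L) next
    blk <- m[, idx, drop = FALSE]
    padded <- cbind(blk[, rep(1L, h), drop = FALSE], blk,
                    blk[, rep(ncol(blk), h), drop = FALSE])
    nc <- length(idx)
    sm <- matrix(0, nrow(m), nc)
    for (kk in seq_len(k))
      sm <- sm + (1 / k) * padded[, kk:(kk + nc - 1L), drop = FALSE]
    out[, idx] <- sm
  }
  out
}

.includedCols <- function(width, onRegion) {
  cols0 <- seq_len(width) - 1L
  !(cols0 >= onRegion[1] & cols0 < onRegion[2])
}

#' Detect the posterior retinal pigment epithelium
#'
#' For each included A-scan the brightest axially-smoothed band is located;
#' the posterior RPE depth is the last pixel of the contiguous run around
#' the peak whose intensity stays within `rpeBandFrac` of the peak
#' (measured above the column minimum). The profile is median-filtered
#' across A-scans and excluded or undetectable columns are filled by
#' linear interpolation.
#'
#' The frame is rejected as unusable when fewer than `minUsableColFrac` of
#' the included columns show a band, or when the detected edge profile is
#' incoherent across columns (median absolute neighbour difference above
#' `maxEdgeCoherencePx`), as happens for structureless frames.
#'
#' @param frame numeric matrix (rows = depth, columns = A-scans).
#' @param onRegion 0-based half-open column interval to exclude.
#' @param control a [segmentationControl()] list.
#' @return Numeric vector of 0-based posterior-RPE depths, one per column.
#' @export
detectRPE <- function(frame, onRegion = c(0L, 0L),
                      control = segmentationControl()) {
  if (!is.matrix(frame) || !length(frame)) stop("frame must be a matrix")
  d <- nrow(frame); w <- ncol(frame)
  inc <- .includedCols(w, onRegion)
  lat <- .lateralSmooth(frame, control$lateralWindow, inc)
  sm <- .axialSmooth(lat, control$rpeAxialWindow)
  edge <- rep(NA_real_, w)
  for (j in which(inc)) {
    col <- sm[, j]
    lo <- min(col); peak <- max(col)
    if (peak - lo <= 1e-12) next        # no contrast: undetectable
    im <- which.max(col)
    # the axially smoothed column locates the band robustly; the edge run
    # itself is traced on the unsmoothed-in-depth profile so axial
    # smoothing cannot shift the posterior boundary
    cl <- lat[, j]
    lo2 <- min(cl)
    thr <- lo2 + control$rpeBandFrac * (max(cl[max(1, im - 4):min(d, im + 4)])
                                        - lo2)
    hi <- im
    while (hi < d && cl[hi + 1L] >= thr) hi <- hi + 1L
    while (hi > 1L && cl[hi] < thr) hi <- hi - 1L
    edge[j] <- hi - 1L                  # 0-based posterior edge
  }
  det <- !is.na(edge) & inc
  if (sum(det) < control$minUsableColFrac * sum(inc))
    .unusable("no bright band detectable in most included columns")
  # coherence across columns spaced a lateral window apart (closer
  # columns share smoothed pixels, so neighbours are trivially coherent
  # even in pure noise)
  dj <- which(det)
  step <- max(1L, as.integer(control$lateralWindow))
  dj <- dj[seq(1L, length(dj), by = step)]
  dif <- abs(diff(edge[dj]))
  if (length(dif) && stats::median(dif) > control$maxEdgeCoherencePx)
    .unusable("RPE edge profile incoherent across A-scans")
  # median filter across A-scans, per contiguous included run
  k <- control$rpeMedianWindow
  if (k %% 2 == 0) k <- k + 1
  runs <- rle(inc)
  pos <- cumsum(c(1L, runs$lengths))
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    idx <- pos[r]:(pos[r + 1L] - 1L)
    v <- edge[idx]
    ok <- !is.na(v)
    if (sum(ok) >= 2L) {
      v[!ok] <- stats::approx(idx[ok], v[ok], xout = idx[!ok],
                              rule = 2)$y
      kk <- min(k, if (length(v) %% 2L == 0L) length(v) - 1L else length(v))
      if (kk >= 3L) v <- stats::runmed(v, kk, endrule = "median")
      edge[idx] <- v
    }
  }
  # fill excluded / still-missing columns by interpolation across the frame
  ok <- !is.na(edge)
  if (sum(ok) < 2L) .unusable("too few columns with a detectable RPE band")
  edge[!ok] <- stats::approx(which(ok), edge[ok], xout = which(!ok),
                             rule = 2)$y
  edge
}

#' Flatten a frame with respect to the posterior RPE
#'
#' Each included A-scan is shifted axially (with edge-value padding) so its
#' posterior RPE lands on a common reference row; the two sides of the
#' optic-nerve gap are flattened independently, each to the rounded median
#' of its own RPE profile. The shift map is returned so depths can be
#' mapped back to the original frame (original = flattened - shift).
#'
#' @param frame numeric matrix.
#' @param rpeDepthPx 0-based posterior-RPE depth per column.
#' @param onRegion 0-based half-open exclusion interval.
#' @return list with class `flattenedFrame`: `frame` (shifted matrix),
#'   `shiftPx` (integer per column), `refRows` (named per-side reference
#'   depths), `onRegion`.
#' @export
flattenFrame <- function(frame, rpeDepthPx, onRegion = c(0L, 0L)) {
  d <- nrow(frame); w <- ncol(frame)
  stopifnot(length(rpeDepthPx) == w)
  inc <- .includedCols(w, onRegion)
  cols0 <- seq_len(w) - 1L
  side <- ifelse(!inc, NA_character_,
                 ifelse(onRegion[2] > onRegion[1] & cols0 >= onRegion[2],
                        "right", "left"))
  shift <- integer(w)
  refRows <- c(left = NA_real_, right = NA_real_)
  for (s in c("left", "right")) {
    js <- which(!is.na(side) & side == s)
    if (!length(js)) next
    ref <- round(stats::median(rpeDepthPx[js]))
    refRows[s] <- ref
    shift[js] <- as.integer(ref - round(rpeDepthPx[js]))
  }
  if (any(abs(shift) >= d)) stop("flattening shift exceeds frame depth")
  flat <- frame
  for (j in which(shift != 0L)) {
    s <- shift[j]
    col <- frame[, j]
    if (s > 0) flat[, j] <- c(rep(col[1L], s), col[seq_len(d - s)])
    else flat[, j] <- c(col[(1L - s):d], rep(col[d], -s))
  }
  structure(list(frame = flat, shiftPx = shift, refRows = refRows,
                 onRegion = as.integer(onRegion)),
            class = c("flattenedFrame", "list"))
}

#' Undo a flattening transform
#'
#' Inverts the per-column shifts of [flattenFrame()]. Rows introduced by
#' edge padding are restored from padding again, so the round-trip is exact
#' except within those padded rows.
#'
#' @param flat a `flattenedFrame` as returned by [flattenFrame()].
#' @return The unshifted numeric matrix.
#' @export
unflattenFrame <- function(flat) {
  stopifnot(inherits(flat, "flattenedFrame"))
  d <- nrow(flat$frame)
  out <- flat$frame
  for (j in which(flat$shiftPx != 0L)) {
    s <- -flat$shiftPx[j]
    col <- flat$frame[, j]
    if (s > 0) out[, j] <- c(rep(col[1L], s), col[seq_len(d - s)])
    else out[, j] <- c(col[(1L - s):d], rep(col[d], -s))
  }
  out
}

#' Inflection-point candidates along one A-scan
#'
#' Candidate CSI locations are the depths below the RPE where the second
#' difference of the Gaussian-smoothed intensity profile changes sign and
#' the local intensity transition is dark-to-bright (positive first
#' difference) - the signature of passing from a choroidal vessel into the
#' sclera. Each candidate carries its local gradient magnitude.
#'
#' @param ascan numeric intensity profile (length > 3).
#' @param rpeDepthPx 0-based RPE depth; only depths strictly below
#'   (greater than) this are searched.
#' @param smoothingSigma Gaussian sigma in pixels.
#' @return data.frame with columns `depth` (0-based) and `grad`.
#' @export
findInflectionNodes <- function(ascan, rpeDepthPx, smoothingSigma = 2) {
  if (length(ascan) <= 3L) stop("profile too short")
  m <- .gaussSmooth(matrix(ascan, ncol = 1), smoothingSigma)[, 1]
  .nodesFromSmoothed(m, rpeDepthPx)
}

# Shared candidate extraction from an already-smoothed profile (single
# A-scan front-end over the same matrix implementation).
.nodesFromSmoothed <- function(m, rpeDepthPx) {
  nd <- .frameNodes(matrix(m, ncol = 1), 1L, rpeDepthPx)[[1]]
  data.frame(depth = nd$depth, grad = nd$grad)
}

#' Minimum-cost surface search through inflection nodes
#'
#' Finds the minimum-cost left-to-right path selecting one node per column.
#' Node cost is `2 - g + 1e-6` where `g` is the node's dark-to-bright
#' gradient min-max normalized over all supplied nodes (the edge
#' probability: strong boundaries are cheap); the path cost is the sum of
#' node costs. Transitions between adjacent columns are forbidden when the
#' depth difference exceeds `maxJumpPx` (scaled by the column gap when
#' intervening columns carry no nodes). Columns whose nodes are all
#' unreachable are dropped from the chain and bridged by linear
#' interpolation, so an isolated outlier candidate cannot drag the surface
#' with it.
#'
#' @param nodes list with one element per column: a data.frame with
#'   columns `depth` and `grad` (possibly empty / NULL).
#' @param maxJumpPx maximum inter-column depth change in pixels.
#' @return list: `depthPx` (numeric per column, interpolated where no node
#'   was chosen), `cost` (total path cost), `chosen` (logical per column:
#'   TRUE where a node was selected).
#' @export
graphSearchCSI <- function(nodes, maxJumpPx = 15) {
  m <- length(nodes)
  sizes <- vapply(nodes, function(x)
    if (is.null(x)) 0L else length(x$depth), integer(1))
  active <- which(sizes > 0L)
  if (length(active) < 2L)
    .unusable("fewer than two columns with CSI candidates")
  allG <- unlist(lapply(nodes[active], function(x) x$grad))
  gmin <- min(allG); gmax <- max(allG)
  norm <- function(g) if (gmax > gmin) (g - gmin) / (gmax - gmin)
                      else rep(1, length(g))
  costs <- lapply(nodes, function(x) {
    if (is.null(x) || !length(x$depth)) numeric(0)
    else 2 - norm(x$grad) + 1e-6
  })

  dp <- list(); bp <- list(); used <- integer(0)
  for (c0 in active) {
    nd <- nodes[[c0]]$depth
    nc <- costs[[c0]]
    if (!length(used)) {
      dp[[as.character(c0)]] <- nc
      bp[[as.character(c0)]] <- rep(0L, length(nc))
      used <- c0
      next
    }
    prev <- used[length(used)]
    allowed <- maxJumpPx * (c0 - prev)
    pd <- nodes[[prev]]$depth
    pv <- dp[[as.character(prev)]]
    best <- rep(Inf, length(nd)); par <- rep(0L, length(nd))
    for (k in seq_along(nd)) {
      feas <- which(abs(nd[k] - pd) <= allowed & is.finite(pv))
      if (length(feas)) {
        b <- feas[which.min(pv[feas])]
        best[k] <- pv[b] + nc[k]
        par[k] <- b
      }
    }
    if (all(!is.finite(best))) next     # column unreachable: drop it
    dp[[as.character(c0)]] <- best
    bp[[as.character(c0)]] <- par
    used <- c(used, c0)
  }
  if (length(used) < 2L) .unusable("no feasible CSI path")
  last <- used[length(used)]
  lv <- dp[[as.character(last)]]
  k <- which.min(lv)
  total <- lv[k]
  depth <- rep(NA_real_, m)
  for (i in rev(seq_along(used))) {
    c0 <- used[i]
    depth[c0] <- nodes[[c0]]$depth[k]
    k <- bp[[as.character(c0)]][k]
  }
  chosen <- !is.na(depth)
  miss <- which(!chosen)
  if (length(miss))
    depth[miss] <- stats::approx(which(chosen), depth[chosen],
                                 xout = miss, rule = 2)$y
  list(depthPx = depth, cost = total, chosen = chosen)
}

#' Mean choroidal thickness of one frame
#'
#' Average over included columns of `(CSI - RPE) * axial spacing`.
#'
#' @param csiDepthPx,rpeDepthPx 0-based depth profiles (NA allowed).
#' @param axialSpacingUm axial spacing, micrometres per pixel.
#' @param include logical per column; columns outside it contribute
#'   nothing.
#' @return Mean thickness in micrometres, or `NA` when no column has both
#'   depths.
#' @export
choroidalThickness <- function(csiDepthPx, rpeDepthPx, axialSpacingUm,
                               include = NULL) {
  stopifnot(length(csiDepthPx) == length(rpeDepthPx), axialSpacingUm > 0)
  ok <- !is.na(csiDepthPx) & !is.na(rpeDepthPx)
  if (!is.null(include)) ok <- ok & include
  if (!any(ok)) return(NA_real_)
  max(mean((csiDepthPx[ok] - rpeDepthPx[ok]) * axialSpacingUm), 0)
}

#' Segment a single B-scan frame
#'
#' Runs RPE detection, flattening, inflection-node extraction and the graph
#' search (each side of the optic-nerve gap independently), then maps the
#' CSI back to unflattened coordinates and averages the choroidal
#' thickness.
#'
#' @param frame numeric matrix.
#' @param onRegion 0-based half-open exclusion interval.
#' @param axialSpacingUm axial spacing (um/px).
#' @param control a [segmentationControl()].
#' @return list: `rpeDepthPx`, `csiDepthPx` (NA in the excluded region),
#'   `chtUm`, `usable`, `reason`.
#' @export
segmentFrame <- function(frame, onRegion = c(0L, 0L), axialSpacingUm,
                         control = segmentationControl()) {
  res <- tryCatch({
    rpe <- detectRPE(frame, onRegion, control)
    flat <- flattenFrame(frame, rpe, onRegion)
    w <- ncol(frame)
    inc <- .includedCols(w, onRegion)
    sm <- .gaussSmooth(.lateralSmooth(flat$frame, control$lateralWindow,
                                      inc),
                       control$smoothingSigma)
    csi <- rep(NA_real_, w)
    cost <- 0
    cols0 <- seq_len(w) - 1L
    sides <- if (onRegion[2] > onRegion[1])
      list(which(cols0 < onRegion[1]), which(cols0 >= onRegion[2]))
    else list(seq_len(w))
    anySide <- FALSE
    minDepth <- rep(Inf, w)
    for (si in seq_along(sides)) {
      js <- sides[[si]]
      if (!length(js)) next
      minDepth[js] <- flat$refRows[[if (length(sides) > 1 && si == 2)
        "right" else "left"]]
    }
    allNodes <- .frameNodes(sm, which(inc), minDepth)
    for (si in seq_along(sides)) {
      js <- sides[[si]]
      if (length(js) < 2L) next
      nodes <- allNodes[as.character(js)]
      path <- tryCatch(graphSearchCSI(nodes, control$maxJumpPx),
                       ocupulseUnusableFrame = function(e) NULL)
      if (is.null(path)) next
      csi[js] <- path$depthPx - flat$shiftPx[js]   # back to original coords
      cost <- cost + path$cost
      anySide <- TRUE
    }
    if (!anySide) .unusable("no feasible CSI path on either side")
    cht <- choroidalThickness(csi, rpe, axialSpacingUm, include = inc)
    if (is.na(cht)) .unusable("no columns with both RPE and CSI depths")
    list(rpeDepthPx = rpe, csiDepthPx = csi, chtUm = cht, usable = TRUE,
         reason = "")
  }, ocupulseUnusableFrame = function(e) {
    list(rpeDepthPx = NULL, csiDepthPx = NULL, chtUm = NA_real_,
         usable = FALSE, reason = conditionMessage(e))
  })
  res
}

#' Segment every frame of a sequence
#'
#' Applies [segmentFrame()] to each frame independently (the pulsatile
#' analysis happens afterwards in time, so no temporal regularization is
#' used). Unusable frames are dropped with a logged reason; the per-frame
#' (timestamp, ChT) pairs form the raw-stage thickness waveform.
#'
#' @param x a [BScanSequence-class].
#' @param control a [segmentationControl()].
#' @param details if `TRUE`, also return the full
#'   [SegmentationResult-class].
#' @return A raw-stage [ThicknessWaveform-class], or (with
#'   `details = TRUE`) a list `waveform` / `segmentation`.
#' @export
segmentSequence <- function(x, control = segmentationControl(),
                            details = FALSE) {
  stopifnot(is(x, "BScanSequence"))
  n <- frameCount(x)
  w <- ncol(frameData(x, 1))
  rpeM <- matrix(NA_real_, n, w)
  csiM <- matrix(NA_real_, n, w)
  cht <- rep(NA_real_, n)
  usable <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    r <- segmentFrame(frameData(x, i), onRegion(x), axialSpacing(x),
                      control)
    usable[i] <- r$usable
    reason[i] <- r$reason
    if (r$usable) {
      rpeM[i, ] <- r$rpeDepthPx
      csiM[i, ] <- r$csiDepthPx
      cht[i] <- r$chtUm
    }
  }
  if (sum(usable) < 2L)
    stop("fewer than two usable frames; cannot build a thickness waveform")
  seg <- new("SegmentationResult", rpeDepthPx = rpeM, csiDepthPx = csiM,
             chtUm = cht, usable = usable, dropReason = reason)
  wav <- thicknessWaveform(scanTimes(x)[usable], cht[usable],
                           stage = "raw",
                           params = list(nFrames = n,
                                         nUsable = sum(usable),
                                         control = unclass(control)))
  if (details) list(waveform = wav, segmentation = seg) else wav
}
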