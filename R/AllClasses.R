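#' @import methods
NULL

#' BScanSequence: a time-stamped stack of OCT B-scan frames
#'
#' Container for a dynamic OCT acquisition: a list of 2-D grayscale frames
#' (rows = depth, increasing away from the vitreous; columns = A-scans),
#' strictly increasing per-frame timestamps, the axial pixel spacing, and a
#' half-open column interval marking the optic-nerve-head region that is
#' excluded from segmentation.
#'
#' Depth and column coordinates are 0-based throughout the package, matching
#' the JSON sidecar convention; the optic-nerve region is `[lo, hi)`.
#'
#' @slot frames list of numeric matrices, all of identical dimension.
#' @slot timestamps numeric vector of per-frame acquisition times in seconds,
#'   strictly increasing.
#' @slot axialSpacing axial pixel spacing in micrometres per pixel.
#' @slot onRegion integer vector `c(lo, hi)`, the 0-based half-open column
#'   interval of the optic-nerve-head exclusion zone (`lo == hi` means none).
#'
#' @seealso [simulateBScans()], [segmentSequence()], [readBScanSequence()]
#' @export
setClass("BScanSequence",
  representation(
    frames = "list",
    timestamps = "numeric",
    axialSpacing = "numeric",
    onRegion = "integer"
  )
)

setValidity("BScanSequence", function(object) {
  msg <- character()
  n <- length(object@frames)
  if (n < 1L) msg <- c(msg, "sequence must contain at least one frame")
  if (n >= 1L) {
    if (!all(vapply(object@frames, is.matrix, logical(1))))
      msg <- c(msg, "all frames must be matrices")
    dims <- vapply(object@frames, dim, integer(2))
    if (n > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all frames must share the same dimensions")
  }
  if (length(object@timestamps) != n)
    msg <- c(msg, "one timestamp per frame required")
  if (n > 1L && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(object@axialSpacing) != 1L || object@axialSpacing <= 0)
    msg <- c(msg, "axialSpacing must be a single positive number")
  if (length(object@onRegion) != 2L)
    msg <- c(msg, "onRegion must be c(lo, hi)")
  else if (n >= 1L) {
    w <- ncol(object@frames[[1]])
    if (object@onRegion[1] < 0L || object@onRegion[1] > object@onRegion[2] ||
        object@onRegion[2] > w)
      msg <- c(msg, "onRegion must satisfy 0 <= lo <= hi <= width")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BScanSequence
#'
#' @param frames list of numeric matrices (rows = depth, columns = A-scans).
#' @param timestamps per-frame times in seconds, strictly increasing.
#' @param axialSpacing axial spacing in micrometres per pixel.
#' @param onRegion 0-based half-open column interval `c(lo, hi)` to exclude.
#' @return A [BScanSequence-class] object.
#' @export
BScanSequence <- function(frames, timestamps, axialSpacing,
                          onRegion = c(0L, 0L)) {
  new("BScanSequence", frames = frames, timestamps = as.numeric(timestamps),
      axialSpacing = as.numeric(axialSpacing),
      onRegion = as.integer(onRegion))
}

#' GroundTruth: the known quantities behind a simulated B-scan sequence
#'
#' Records everything the simulator knows: the noise-free choroidal
#' thickness per frame, its mean peak-to-valley amplitude, and the exact
#' RPE and CSI depth maps, so segmentation and waveform stages can be tested
#' against an oracle.
#'
#' @slot chtUm noise-free mean choroidal thickness per frame (micrometres).
#' @slot trueDeltaTUm mean peak-to-valley of the noise-free pulsatile ChT
#'   signal (micrometres).
#' @slot rpeDepthPx matrix (frames x A-scans) of true posterior-RPE depths,
#'   0-based pixels.
#' @slot csiDepthPx matrix (frames x A-scans) of true CSI depths, 0-based
#'   pixels; `NA` inside the optic-nerve region.
#' @slot timestamps per-frame times in seconds.
#' @export
setClass("GroundTruth",
  representation(
    chtUm = "numeric",
    trueDeltaTUm = "numeric",
    rpeDepthPx = "matrix",
    csiDepthPx = "matrix",
    timestamps = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  n <- length(object@timestamps)
  msg <- character()
  if (length(object@chtUm) != n)
    msg <- c(msg, "chtUm must have one value per frame")
  if (nrow(object@rpeDepthPx) != n || nrow(object@csiDepthPx) != n)
    msg <- c(msg, "depth maps must have one row per frame")
  if (length(object@trueDeltaTUm) != 1L || object@trueDeltaTUm < 0)
    msg <- c(msg, "trueDeltaTUm must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' SimulatedBScans: a simulated sequence together with its ground truth
#'
#' @slot sequence the simulated [BScanSequence-class].
#' @slot truth the matching [GroundTruth-class].
#' @slot params the simulation parameter list used.
#' @seealso [simulateBScans()]
#' @export
setClass("SimulatedBScans",
  representation(
    sequence = "BScanSequence",
    truth = "GroundTruth",
    params = "list"
  )
)

#' SegmentationResult: per-frame layer depths and choroidal thickness
#'
#' @slot rpeDepthPx matrix (frames x A-scans) of posterior-RPE depths in
#'   0-based pixels; `NA` for unusable frames.
#' @slot csiDepthPx matrix (frames x A-scans) of choroidal-scleral-interface
#'   depths; `NA` inside the optic-nerve region and for unusable frames.
#' @slot chtUm mean choroidal thickness per frame in micrometres (`NA` for
#'   unusable frames).
#' @slot usable logical per frame.
#' @slot dropReason character per frame ("" when usable).
#' @export
setClass("SegmentationResult",
  representation(
    rpeDepthPx = "matrix",
    csiDepthPx = "matrix",
    chtUm = "numeric",
    usable = "logical",
    dropReason = "character"
  )
)

setValidity("SegmentationResult", function(object) {
  n <- length(object@chtUm)
  msg <- character()
  if (nrow(object@rpeDepthPx) != n || nrow(object@csiDepthPx) != n ||
      length(object@usable) != n || length(object@dropReason) != n)
    msg <- c(msg, "per-frame slots must agree in length")
  ok <- !is.na(object@chtUm)
  if (any(object@chtUm[ok] < 0))
    msg <- c(msg, "choroidal thickness must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ThicknessWaveform: the choroidal-thickness time series at one stage
#'
#' The pulsatile analysis proceeds through four stages: `raw` (per-usable-
#' frame ChT at irregular acquisition times), `cleaned` (MAD outliers
#' removed), `uniform` (anti-aliased resampling to a uniform grid) and
#' `filtered` (heart-rate band-pass, zero mean). Each object keeps the
#' parameters that produced it and its full parent chain in `history`,
#' so any result can be audited back to the raw series.
#'
#' @slot stage one of `"raw"`, `"cleaned"`, `"uniform"`, `"filtered"`.
#' @slot times times in seconds, strictly increasing.
#' @slot cht choroidal thickness values in micrometres (zero-mean at the
#'   filtered stage).
#' @slot sampleRate sampling rate in Hz (`NA` before the uniform stage).
#' @slot heartRate heart rate in Hz used by the band-pass (`NA` before the
#'   filtered stage).
#' @slot deltaT mean peak-to-valley amplitude in micrometres (`NA` until
#'   computed on the filtered stage).
#' @slot params list of the parameters that produced this stage.
#' @slot history list of the earlier-stage objects (oldest first).
#' @export
setClass("ThicknessWaveform",
  representation(
    stage = "character",
    times = "numeric",
    cht = "numeric",
    sampleRate = "numeric",
    heartRate = "numeric",
    deltaT = "numeric",
    params = "list",
    history = "list"
  )
)

setValidity("ThicknessWaveform", function(object) {
  msg <- character()
  if (!object@stage %in% c("raw", "cleaned", "uniform", "filtered"))
    msg <- c(msg, "unknown stage")
  if (length(object@times) != length(object@cht))
    msg <- c(msg, "times and cht must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!is.na(object@deltaT) && object@deltaT < 0)
    msg <- c(msg, "deltaT must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a raw-stage ThicknessWaveform
#'
#' @param times times in seconds, strictly increasing.
#' @param cht choroidal thickness values in micrometres.
#' @param stage stage label, default `"raw"`.
#' @param sampleRate sampling rate in Hz for uniform stages.
#' @param params parameter list to record.
#' @return A [ThicknessWaveform-class] object.
#' @export
thicknessWaveform <- function(times, cht, stage = "raw",
                              sampleRate = NA_real_, params = list()) {
  new("ThicknessWaveform", stage = stage, times = as.numeric(times),
      cht = as.numeric(cht), sampleRate = as.numeric(sampleRate),
      heartRate = NA_real_, deltaT = NA_real_, params = params,
      history = list())
}
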