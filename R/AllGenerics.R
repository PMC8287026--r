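#' @rdname BScanSequence-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("frameCount", function(x) standardGeneric("frameCount"))

#' @rdname BScanSequence-class
#' @param i frame index (1-based).
#' @export
setGeneric("frameData", function(x, i) standardGeneric("frameData"))

#' @rdname BScanSequence-class
#' @export
setGeneric("scanTimes", function(x) standardGeneric("scanTimes"))

#' @rdname BScanSequence-class
#' @export
setGeneric("axialSpacing", function(x) standardGeneric("axialSpacing"))

#' @rdname BScanSequence-class
#' @export
setGeneric("onRegion", function(x) standardGeneric("onRegion"))

#' @rdname SimulatedBScans-class
#' @export
setGeneric("scanSequence", function(x) standardGeneric("scanSequence"))

#' @rdname SimulatedBScans-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("chtSeries", function(x) standardGeneric("chtSeries"))

#' @rdname ThicknessWaveform-class
#' @export
setGeneric("waveStage", function(x) standardGeneric("waveStage"))

#' @rdname ThicknessWaveform-class
#' @export
setGeneric("deltaT", function(x) standardGeneric("deltaT"))

setMethod("frameCount", "BScanSequence", function(x) length(x@frames))
setMethod("frameData", "BScanSequence", function(x, i) x@frames[[i]])
setMethod("scanTimes", "BScanSequence", function(x) x@timestamps)
setMethod("axialSpacing", "BScanSequence", function(x) x@axialSpacing)
setMethod("onRegion", "BScanSequence", function(x) x@onRegion)

setMethod("scanSequence", "SimulatedBScans", function(x) x@sequence)
setMethod("groundTruth", "SimulatedBScans", function(x) x@truth)

setMethod("chtSeries", "SegmentationResult", function(x) x@chtUm)
setMethod("chtSeries", "ThicknessWaveform", function(x) x@cht)

setMethod("scanTimes", "ThicknessWaveform", function(x) x@times)
setMethod("waveStage", "ThicknessWaveform", function(x) x@stage)
setMethod("deltaT", "ThicknessWaveform", function(x) x@deltaT)

setMethod("show", "BScanSequence", function(object) {
  d <- dim(object@frames[[1]])
  cat("BScanSequence:", length(object@frames), "frames,",
      d[1], "x", d[2], "px\n")
  cat("  time span:", sprintf("%.3f", diff(range(object@timestamps))),
      "s; axial spacing:", object@axialSpacing, "um/px\n")
  cat("  optic-nerve region (cols, 0-based): [",
      object@onRegion[1], ",", object@onRegion[2], ")\n")
})

setMethod("show", "SimulatedBScans", function(object) {
  cat("SimulatedBScans with ground truth\n")
  show(object@sequence)
  cat("  true delta-t:", sprintf("%.3f", object@truth@trueDeltaTUm), "um\n")
})

setMethod("show", "SegmentationResult", function(object) {
  n <- length(object@chtUm)
  cat("SegmentationResult:", n, "frames,", sum(object@usable), "usable\n")
  ok <- object@chtUm[object@usable]
  if (length(ok))
    cat("  ChT (um): mean", sprintf("%.1f", mean(ok)),
        "range", sprintf("[%.1f, %.1f]", min(ok), max(ok)), "\n")
})

setMethod("show", "ThicknessWaveform", function(object) {
  cat("ThicknessWaveform [", object@stage, "]: ",
      length(object@times), " samples\n", sep = "")
  if (!is.na(object@sampleRate))
    cat("  sample rate:", sprintf("%.2f", object@sampleRate), "Hz\n")
  if (!is.na(object@heartRate))
    cat("  heart rate:", sprintf("%.3f", object@heartRate), "Hz\n")
  if (!is.na(object@deltaT))
    cat("  delta-t:", sprintf("%.3f", object@deltaT), "um\n")
})

#' Plot a thickness waveform
#'
#' @param x a [ThicknessWaveform-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature("ThicknessWaveform", "missing"),
  function(x, y, ...) {
    graphics::plot(x@times, x@cht, type = "l", xlab = "time (s)",
                   ylab = "ChT (um)",
                   main = paste("ChT waveform,", x@stage, "stage"), ...)
  })
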