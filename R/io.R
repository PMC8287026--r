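# Formats and configuration: multi-page TIFF + JSON sidecar for B-scan
# stacks, CSV for waveforms and subject tables, strict YAML pipeline
# configuration, and the end-to-end driver with a reproducibility
# manifest.

#' Write a B-scan sequence as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 16-bit grayscale pages of `<stem>.tif`; the
#' sidecar `<stem>.json` carries `timestamps_s`,
#' `axial_spacing_um_per_px` and `on_region` (0-based, half-open).
#'
#' @param x a [BScanSequence-class].
#' @param stem output path without extension.
#' @return Invisibly, the two paths written.
#' @export
writeBScanSequence <- function(x, stem) {
  stopifnot(is(x, "BScanSequence"))
  tifPath <- paste0(stem, ".tif")
  jsonPath <- paste0(stem, ".json")
  frames <- lapply(x@frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, tifPath, bits.per.sample = 16L)
  jsonlite::write_json(
    list(timestamps_s = x@timestamps,
         axial_spacing_um_per_px = x@axialSpacing,
         on_region = x@onRegion),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(tifPath, jsonPath))
}

#' Read a B-scan sequence from multi-page TIFF plus JSON sidecar
#'
#' @param path the TIFF path or the common stem of `<stem>.tif` /
#'   `<stem>.json`.
#' @return A [BScanSequence-class].
#' @export
readBScanSequence <- function(path) {
  stem <- sub("\\.tiff?$", "", path)
  tifPath <- if (file.exists(path) && grepl("\\.tiff?$", path)) path
             else paste0(stem, ".tif")
  jsonPath <- paste0(stem, ".json")
  if (!file.exists(tifPath)) stop("stack not found: ", tifPath)
  if (!file.exists(jsonPath)) stop("sidecar not found: ", jsonPath)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  if (is.null(meta$timestamps_s))
    stop("sidecar lacks timestamps_s; refusing to assume uniform timing")
  if (is.null(meta$axial_spacing_um_per_px))
    stop("sidecar lacks axial_spacing_um_per_px")
  frames <- tiff::readTIFF(tifPath, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (length(dim(f)) == 3L) f <- f[, , 1]
    if (!is.matrix(f))
      stop(sprintf("frame %d is not a 2-D grayscale image", i))
    f
  })
  if (length(frames) != length(meta$timestamps_s))
    stop(sprintf(
      "frame count (%d) does not match sidecar timestamps (%d)",
      length(frames), length(meta$timestamps_s)))
  onr <- if (is.null(meta$on_region)) c(0L, 0L)
         else as.integer(meta$on_region)
  BScanSequence(frames, meta$timestamps_s,
                meta$axial_spacing_um_per_px, onr)
}

#' Write a thickness waveform as CSV plus JSON parameter sidecar
#'
#' @param wave a [ThicknessWaveform-class].
#' @param stem output path without extension.
#' @return Invisibly, the paths written.
#' @export
writeWaveform <- function(wave, stem) {
  stopifnot(is(wave, "ThicknessWaveform"))
  csvPath <- paste0(stem, ".csv")
  jsonPath <- paste0(stem, ".json")
  utils::write.csv(data.frame(time_s = wave@times, cht_um = wave@cht),
                   csvPath, row.names = FALSE)
  jsonlite::write_json(
    list(stage = wave@stage, sample_rate_hz = wave@sampleRate,
         heart_rate_hz = wave@heartRate, delta_t_um = wave@deltaT,
         params = wave@params),
    jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csvPath, jsonPath))
}

#' Read a thickness waveform from CSV (plus optional JSON sidecar)
#'
#' @param stem the CSV path or common stem.
#' @return A [ThicknessWaveform-class].
#' @export
readWaveform <- function(stem) {
  stem <- sub("\\.csv$", "", stem)
  df <- utils::read.csv(paste0(stem, ".csv"))
  if (!all(c("time_s", "cht_um") %in% names(df)))
    stop("waveform CSV must have columns time_s, cht_um")
  jsonPath <- paste0(stem, ".json")
  if (file.exists(jsonPath)) {
    meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    w <- thicknessWaveform(df$time_s, df$cht_um,
                           stage = meta$stage %||% "raw",
                           sampleRate = meta$sample_rate_hz %||% NA_real_,
                           params = as.list(meta$params %||% list()))
    if (!is.null(meta$heart_rate_hz) && !is.na(meta$heart_rate_hz))
      w@heartRate <- meta$heart_rate_hz
    if (!is.null(meta$delta_t_um) && !is.na(meta$delta_t_um))
      w@deltaT <- meta$delta_t_um
    w
  } else thicknessWaveform(df$time_s, df$cht_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a segmentation result as JSON
#'
#' Stores the per-frame mean choroidal thickness, usability flags and
#' drop reasons, plus the full RPE/CSI depth maps (0-based pixels).
#'
#' @param seg a [SegmentationResult-class].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
writeSegmentation <- function(seg, path) {
  stopifnot(is(seg, "SegmentationResult"))
  jsonlite::write_json(
    list(cht_um = seg@chtUm, usable = seg@usable,
         drop_reason = seg@dropReason,
         rpe_depth_px = round(seg@rpeDepthPx, 2),
         csi_depth_px = round(seg@csiDepthPx, 2)),
    path, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read / write subject tables
#'
#' Thin CSV wrappers with a minimal column check (`iop_mmhg` and
#' `opa_mmhg` must be present on read).
#'
#' @param path CSV file path.
#' @return [readSubjects()]: a data.frame.
#' @export
readSubjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("iop_mmhg", "opa_mmhg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subject table lacks required columns: ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname readSubjects
#' @param table data.frame of subject records.
#' @export
writeSubjects <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Full pipeline configuration
#'
#' Bundles the per-stage tuning lists. The defaults reproduce the
#' published processing constants without user input: the 3-MAD outlier
#' rule, the 0.5-3x heart-rate band-pass, and the thin-shell volume model.
#'
#' @param segmentation a [segmentationControl()].
#' @param waveform a [waveformControl()].
#' @param model a [modelControl()].
#' @param stats a [statsControl()].
#' @param seed integer seed recorded in the manifest.
#' @return A named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(segmentation = segmentationControl(),
                           waveform = waveformControl(),
                           model = modelControl(),
                           stats = statsControl(), seed = NULL) {
  structure(list(segmentation = segmentation, waveform = waveform,
                 model = model, stats = stats, seed = seed),
            class = c("pipelineConfig", "list"))
}

.strictCall <- function(fn, args, where) {
  known <- names(formals(fn))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", where,
                 paste(unknown, collapse = ", ")))
  do.call(fn, args)
}

#' Read a pipeline configuration from YAML (strict)
#'
#' Unknown keys at any level are rejected rather than ignored, so the
#' pinned processing constants cannot silently drift through typos.
#'
#' @param path YAML file with optional blocks `segmentation`, `waveform`,
#'   `model` (with nested `schematic_eye`), `stats`, and `seed`.
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("segmentation", "waveform", "model", "stats", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  seg <- .strictCall(segmentationControl,
                     y$segmentation %||% list(), "segmentation")
  wav <- .strictCall(waveformControl, y$waveform %||% list(), "waveform")
  margs <- y$model %||% list()
  eye <- schematicEyeConstants()
  if (!is.null(margs$schematic_eye)) {
    eye <- .strictCall(schematicEyeConstants, margs$schematic_eye,
                       "schematic_eye")
    margs$schematic_eye <- NULL
  }
  if (!is.null(margs$volume_model)) {
    margs$volumeModel <- margs$volume_model
    margs$volume_model <- NULL
  }
  unknown <- setdiff(names(margs), "volumeModel")
  if (length(unknown))
    stop("unknown model key(s): ", paste(unknown, collapse = ", "))
  mod <- modelControl(volumeModel = margs$volumeModel %||% "thin_shell",
                      schematicEye = eye)
  st <- .strictCall(statsControl, y$stats %||% list(), "stats")
  pipelineConfig(seg, wav, mod, st, seed = y$seed)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a [pipelineConfig()].
#' @param path output YAML path.
#' @return Invisibly, `path`.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "pipelineConfig"))
  y <- list(
    segmentation = unclass(config$segmentation),
    waveform = config$waveform[!vapply(config$waveform, is.null,
                                       logical(1))],
    model = list(volume_model = config$model$volumeModel,
                 schematic_eye = unclass(config$model$schematicEye)),
    stats = unclass(config$stats))
  if (!is.null(config$seed)) y$seed <- config$seed
  y$waveform <- unclass(y$waveform)
  attr(y$waveform, "class") <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full estimation pipeline for one eye
#'
#' Segmentation, waveform analysis and the rigidity computation, with
#' per-stage artifacts, a machine-readable run manifest (config hash,
#' seed, package version) and a log line per stage carrying the audit
#' quantities: usable frames, heart rate, delta-t, dV and k. Stage
#' failures abort with a stage tag; artifacts written before the failure
#' are retained.
#'
#' @param stackPath TIFF stack path or stem (see [readBScanSequence()]).
#' @param subject a one-row data.frame, or a CSV path whose first row is
#'   used.
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param heartRateHz heart rate in Hz; default takes the subject's
#'   `heart_rate_hz` field, falling back to spectral estimation.
#' @return list: `record` (subject row with derived fields), `waveform`
#'   (filtered stage), `segmentation`, `manifest` (list, also written as
#'   JSON).
#' @export
runPipeline <- function(stackPath, subject, config = pipelineConfig(),
                        outDir = NULL, heartRateHz = NULL) {
  tag <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.character(subject)) subject <- readSubjects(subject)
  subject <- subject[1, , drop = FALSE]
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  seqc <- tag("input", readBScanSequence(stackPath))
  seg <- tag("segmentation",
             segmentSequence(seqc, config$segmentation, details = TRUE))
  nUsable <- sum(seg$segmentation@usable)
  message(sprintf("[segmentation] %d/%d frames usable", nUsable,
                  frameCount(seqc)))
  if (!is.null(outDir)) {
    writeWaveform(seg$waveform, file.path(outDir, "waveform_raw"))
    writeSegmentation(seg$segmentation,
                      file.path(outDir, "segmentation.json"))
  }

  hr <- heartRateHz
  if (is.null(hr) && "heart_rate_hz" %in% names(subject) &&
      !is.na(subject$heart_rate_hz))
    hr <- subject$heart_rate_hz
  filtered <- tag("waveform",
                  extractDeltaT(seg$waveform, heartRateHz = hr,
                                control = config$waveform))
  message(sprintf("[waveform] heart rate %.3f Hz, delta-t %.3f um",
                  filtered@heartRate, filtered@deltaT))
  if (!is.null(outDir))
    writeWaveform(filtered, file.path(outDir, "waveform_filtered"))

  record <- tag("rigidity",
                computeSubject(subject, deltaTUm = filtered@deltaT,
                               control = config$model))
  message(sprintf("[rigidity] dV %.4f uL, k %.6f 1/uL", record$dv_ul,
                  record$k_per_ul))

  manifest <- list(
    package = "ocupulse",
    version = as.character(utils::packageVersion("ocupulse")),
    r_version = as.character(getRversion()),
    stack = normalizePath(sub("\\.tiff?$", "", stackPath),
                          mustWork = FALSE),
    seed = config$seed,
    quantities = list(frames_total = frameCount(seqc),
                      frames_usable = nUsable,
                      heart_rate_hz = filtered@heartRate,
                      delta_t_um = filtered@deltaT,
                      dv_ul = record$dv_ul,
                      k_per_ul = record$k_per_ul))
  if (!is.null(outDir)) {
    cfgPath <- file.path(outDir, "config.yaml")
    writePipelineConfig(config, cfgPath)
    manifest$config_md5 <- unname(tools::md5sum(cfgPath))
    writeSubjects(record, file.path(outDir, "subject_derived.csv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(record = record, waveform = filtered,
       segmentation = seg$segmentation, manifest = manifest)
}
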