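# Closed-form biomechanics: pulsatile ocular volume change, Friedenwald
# rigidity, Corvis stiffness parameters, P/V ratio, and the schematic-eye
# axial-length derivation.

#' Pulsatile ocular volume change, thin-shell model
#'
#' The choroid is treated as a thin spherical shell of thickness change
#' `delta-t` at radius `R = AL / 2`, so `dV = 4 pi R^2 dt`. Micro-litres
#' and cubic millimetres coincide.
#'
#' @param alMm axial length in mm.
#' @param deltaTUm pulsatile thickness change in micrometres.
#' @return Volume change in uL.
#' @examples
#' volumeChangeThinShell(24.82, 5)  # 9.677 uL
#' @export
volumeChangeThinShell <- function(alMm, deltaTUm) {
  stopifnot(alMm > 0, deltaTUm >= 0)
  r <- alMm / 2
  4 * pi * r^2 * (deltaTUm / 1000)
}

#' Pulsatile ocular volume change, exact two-sphere difference
#'
#' `dV = (4/3) pi ((R + dt)^3 - R^3)` with `R = AL / 2`.
#'
#' @inheritParams volumeChangeThinShell
#' @return Volume change in uL.
#' @export
volumeChangeExact <- function(alMm, deltaTUm) {
  stopifnot(alMm > 0, deltaTUm >= 0)
  r <- alMm / 2
  dt <- deltaTUm / 1000
  (4 / 3) * pi * ((r + dt)^3 - r^3)
}

#' Friedenwald ocular rigidity coefficient
#'
#' From `ln IOP1 - ln IOP2 = k dV` with the systolic pressure
#' `IOP1 = IOP + OPA` (diastolic reading plus ocular pulse amplitude) and
#' `IOP2 = IOP`: `k = log1p(OPA / IOP) / dV`.
#'
#' @param iopMmhg diastolic IOP reading (mmHg), positive.
#' @param opaMmhg ocular pulse amplitude (mmHg), non-negative.
#' @param dvUl pulsatile volume change (uL), positive.
#' @return Rigidity `k` in 1/uL.
#' @examples
#' friedenwaldRigidity(16, 4, 10)  # log(1.25) / 10
#' @export
friedenwaldRigidity <- function(iopMmhg, opaMmhg, dvUl) {
  if (any(iopMmhg <= 0)) stop("iopMmhg must be positive")
  if (any(opaMmhg < 0)) stop("opaMmhg must be non-negative")
  if (any(dvUl <= 0)) stop("dvUl must be positive")
  log1p(opaMmhg / iopMmhg) / dvUl
}

#' Corneal stiffness parameter at first applanation (SP-A1)
#'
#' `(AP1_adj - bIOP) / deflection at first applanation`.
#'
#' @param ap1AdjMmhg adjusted air pressure at first applanation (mmHg).
#' @param biopMmhg biomechanically corrected IOP (mmHg).
#' @param deltaA1Mm deflection at first applanation (mm), positive.
#' @return SP-A1.
#' @export
stiffnessA1 <- function(ap1AdjMmhg, biopMmhg, deltaA1Mm) {
  if (any(deltaA1Mm <= 0)) stop("deltaA1Mm must be positive")
  (ap1AdjMmhg - biopMmhg) / deltaA1Mm
}

#' Scleral stiffness parameter at highest concavity (SP-HC)
#'
#' `(AP1_adj - bIOP) / (deflection at highest concavity - deflection at
#' first applanation)`.
#'
#' @inheritParams stiffnessA1
#' @param deltaHcMm maximum deflection near highest concavity (mm), must
#'   exceed `deltaA1Mm`.
#' @return SP-HC.
#' @export
stiffnessHC <- function(ap1AdjMmhg, biopMmhg, deltaA1Mm, deltaHcMm) {
  if (any(deltaHcMm <= deltaA1Mm))
    stop("deltaHcMm must exceed deltaA1Mm")
  (ap1AdjMmhg - biopMmhg) / (deltaHcMm - deltaA1Mm)
}

#' Static pressure-volume ratio
#'
#' IOP divided by anterior chamber volume, mmHg per uL.
#'
#' @param iopMmhg IOP in mmHg.
#' @param acvUl anterior chamber volume in uL, positive.
#' @return P/V ratio (mmHg/uL).
#' @export
pvRatio <- function(iopMmhg, acvUl) {
  if (any(acvUl <= 0)) stop("acvUl must be positive")
  iopMmhg / acvUl
}

#' Constants of the simplified paraxial schematic eye
#'
#' The cornea is a single refracting surface of power
#' `(nAqueous - 1) / r`; a thin lens of fixed power sits
#' `corneaLensSepMm` behind it; image space has index `nVitreous`. The
#' chain is calibrated (additive offset) so that an emmetropic eye with
#' the reference corneal radius returns `emmetropicAlMm` exactly.
#'
#' @param nAqueous,nVitreous refractive indices (default 4/3).
#' @param lensPowerD equivalent lens power, dioptres.
#' @param corneaLensSepMm cornea-to-lens separation, mm.
#' @param referenceRadiusMm corneal radius of the emmetropic reference
#'   eye, mm.
#' @param emmetropicAlMm axial length of the emmetropic reference eye, mm.
#' @return A named list of class `schematicEye`.
#' @export
schematicEyeConstants <- function(nAqueous = 4 / 3, nVitreous = 4 / 3,
                                  lensPowerD = 21.76,
                                  corneaLensSepMm = 5.70,
                                  referenceRadiusMm = 7.80,
                                  emmetropicAlMm = 23.89) {
  stopifnot(nAqueous > 1, nVitreous > 1, lensPowerD > 0,
            corneaLensSepMm > 0, referenceRadiusMm > 0,
            emmetropicAlMm > 0)
  structure(list(nAqueous = nAqueous, nVitreous = nVitreous,
                 lensPowerD = lensPowerD,
                 corneaLensSepMm = corneaLensSepMm,
                 referenceRadiusMm = referenceRadiusMm,
                 emmetropicAlMm = emmetropicAlMm),
            class = c("schematicEye", "list"))
}

# uncalibrated vergence-chain axial length (mm)
.alRaw <- function(seD, radiusMm, eye) {
  fc <- (eye$nAqueous - 1) / (radiusMm / 1000)       # corneal power, D
  v1 <- seD + fc                                     # vergence after cornea
  d <- eye$corneaLensSepMm / 1000 / eye$nAqueous     # reduced separation
  denom <- 1 - d * v1
  vLens <- v1 / denom + eye$lensPowerD               # vergence after lens
  if (vLens <= 0) return(NA_real_)
  x <- eye$nVitreous / vLens * 1000                  # image distance, mm
  eye$corneaLensSepMm + x
}

#' Axial length from the schematic eye
#'
#' Paraxial vergence chain of the simplified schematic eye under the
#' axial-ametropia assumption: the corneal power follows from the measured
#' radius, the far-point vergence equals the spherical-equivalent
#' refraction, and the axial length is the image distance of the chain
#' plus a fixed calibration offset anchoring the emmetropic reference eye.
#' Myopic eyes (SE < 0) come out longer, steeper corneas shorter.
#'
#' @param refractionSeD spherical-equivalent refraction, dioptres
#'   (|SE| <= 6 supported).
#' @param cornealRadiusMm corneal radius of curvature, mm.
#' @param eye constants from [schematicEyeConstants()].
#' @return Axial length in mm.
#' @examples
#' axialLengthSchematicEye(0, 7.8)    # emmetropic anchor: 23.89
#' axialLengthSchematicEye(-3, 7.8)   # myope: longer
#' @export
axialLengthSchematicEye <- function(refractionSeD, cornealRadiusMm,
                                    eye = schematicEyeConstants()) {
  stopifnot(cornealRadiusMm > 0)
  if (abs(refractionSeD) > 6)
    stop("spherical equivalent outside the supported +/-6 D range")
  offset <- eye$emmetropicAlMm - .alRaw(0, eye$referenceRadiusMm, eye)
  al <- .alRaw(refractionSeD, cornealRadiusMm, eye) + offset
  if (is.na(al) || al < 15 || al > 35)
    stop("derived axial length outside the physical 15-35 mm range")
  al
}

#' Model configuration for the rigidity computation
#'
#' @param volumeModel `"thin_shell"` (the operative formula) or `"exact"`
#'   (two-sphere difference).
#' @param schematicEye constants from [schematicEyeConstants()].
#' @return A named list of class `modelControl`.
#' @export
modelControl <- function(volumeModel = c("thin_shell", "exact"),
                         schematicEye = schematicEyeConstants()) {
  volumeModel <- match.arg(volumeModel)
  structure(list(volumeModel = volumeModel, schematicEye = schematicEye),
            class = c("modelControl", "list"))
}

#' Derive all biomechanical quantities for one subject
#'
#' Fills the pulsatile volume change (thin-shell by default), the
#' Friedenwald rigidity, the Corvis stiffness parameters when the Corvis
#' fields are present, and the P/V ratio. The axial length is taken from
#' the record when available and otherwise derived from the schematic eye
#' (requires `refraction_se_d` and `corneal_radius_mm`); `al_source`
#' records which.
#'
#' @param record a one-row data.frame (or list) with fields `iop_mmhg`,
#'   `opa_mmhg`, `acv_ul`, and either `al_mm` or
#'   (`refraction_se_d`, `corneal_radius_mm`); optionally
#'   `ap1_adj_mmhg`, `biop_mmhg`, `delta_a1_mm`, `delta_hc_mm`.
#' @param deltaTUm pulsatile thickness change in micrometres (overrides a
#'   `delta_t_um` field).
#' @param control a [modelControl()].
#' @return The record as a one-row data.frame with derived columns
#'   `al_mm`, `al_source`, `delta_t_um`, `dv_ul`, `k_per_ul`, `sp_a1`,
#'   `sp_hc`, `pv_ratio_mmhg_per_ul`.
#' @export
computeSubject <- function(record, deltaTUm = NULL,
                           control = modelControl()) {
  rec <- as.data.frame(as.list(record), stringsAsFactors = FALSE)
  get <- function(f) if (f %in% names(rec) && !is.na(rec[[f]])) rec[[f]]
                     else NULL
  errs <- character(0)
  need <- c("iop_mmhg", "opa_mmhg")
  for (f in need) if (is.null(get(f)))
    errs <- c(errs, sprintf("missing field %s", f))
  if (length(errs)) stop(paste(errs, collapse = "; "))

  al <- get("al_mm")
  if (is.null(al)) {
    if (is.null(get("refraction_se_d")) || is.null(get("corneal_radius_mm")))
      stop("al_mm absent and not derivable (need refraction_se_d and corneal_radius_mm)")
    al <- axialLengthSchematicEye(rec$refraction_se_d,
                                  rec$corneal_radius_mm,
                                  control$schematicEye)
    rec$al_source <- "schematic_eye"
  } else rec$al_source <- "measured"
  rec$al_mm <- al

  dt <- if (!is.null(deltaTUm)) deltaTUm else get("delta_t_um")
  if (is.null(dt)) stop("missing field delta_t_um")
  rec$delta_t_um <- dt
  rec$dv_ul <- if (control$volumeModel == "thin_shell")
    volumeChangeThinShell(al, dt) else volumeChangeExact(al, dt)
  rec$k_per_ul <- friedenwaldRigidity(rec$iop_mmhg, rec$opa_mmhg,
                                      rec$dv_ul)
  corvis <- c("ap1_adj_mmhg", "biop_mmhg", "delta_a1_mm", "delta_hc_mm")
  if (all(vapply(corvis, function(f) !is.null(get(f)), logical(1)))) {
    rec$sp_a1 <- stiffnessA1(rec$ap1_adj_mmhg, rec$biop_mmhg,
                             rec$delta_a1_mm)
    rec$sp_hc <- stiffnessHC(rec$ap1_adj_mmhg, rec$biop_mmhg,
                             rec$delta_a1_mm, rec$delta_hc_mm)
  } else {
    rec$sp_a1 <- NA_real_
    rec$sp_hc <- NA_real_
  }
  rec$pv_ratio_mmhg_per_ul <- if (!is.null(get("acv_ul")))
    pvRatio(rec$iop_mmhg, rec$acv_ul) else NA_real_
  rec
}

#' Derive biomechanical quantities for every subject of a cohort table
#'
#' Applies [computeSubject()] row-wise; rows whose required fields are
#' missing get `NA` derived values and the failure reason in
#' `compute_error`.
#'
#' @param table data.frame of subject records (see [simulateCohort()] for
#'   the column conventions).
#' @param control a [modelControl()].
#' @return The table with derived columns appended.
#' @export
computeCohort <- function(table, control = modelControl()) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    tryCatch(cbind(computeSubject(table[i, , drop = FALSE],
                                  control = control),
                   compute_error = "", stringsAsFactors = FALSE),
             error = function(e) {
               r <- table[i, , drop = FALSE]
               for (f in c("dv_ul", "k_per_ul", "sp_a1", "sp_hc",
                           "pv_ratio_mmhg_per_ul"))
                 r[[f]] <- NA_real_
               r$al_source <- NA_character_
               r$compute_error <- conditionMessage(e)
               r
             })
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (f in setdiff(cols, names(r))) r[[f]] <- NA
    r[, cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
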