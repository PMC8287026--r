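test_that("thin-shell and exact volume change", {
  expect_equal(volumeChangeThinShell(24.82, 5), 4 * pi * 12.41^2 * 0.005)
  expect_equal(volumeChangeThinShell(24.82, 5), 9.677, tolerance = 1e-4)
  expect_equal(volumeChangeThinShell(24, 0), 0)
  expect_equal(volumeChangeThinShell(24, 10),
               2 * volumeChangeThinShell(24, 5))

  expect_equal(volumeChangeExact(24.82, 5), 9.681, tolerance = 1e-4)
  expect_equal(volumeChangeExact(24, 0), 0)

  # thin shell underestimates, within the algebraic bound
  for (al in c(20, 24, 30)) for (dt in c(1, 5, 20)) {
    thin <- volumeChangeThinShell(al, dt)
    exact <- volumeChangeExact(al, dt)
    expect_lt(thin, exact)
    r <- al / 2; dtmm <- dt / 1000
    expect_lte((exact - thin) / exact, 3 * dtmm / r + (dtmm / r)^2)
  }
  expect_error(volumeChangeThinShell(-1, 5))
})

test_that("Friedenwald rigidity from diastolic IOP and OPA", {
  expect_equal(friedenwaldRigidity(16, 4, 10), log(1.25) / 10)
  expect_equal(friedenwaldRigidity(16, 4, 10), (log(20) - log(16)) / 10)
  expect_equal(friedenwaldRigidity(16, 0, 10), 0)
  # scale invariance in pressure
  expect_equal(friedenwaldRigidity(32, 8, 10),
               friedenwaldRigidity(16, 4, 10))
  expect_error(friedenwaldRigidity(16, 4, 0), "dvUl")
  expect_error(friedenwaldRigidity(0, 4, 10), "iop")
})

test_that("Friedenwald round-trip and monotonicity", {
  set.seed(1)
  for (i in 1:50) {
    k <- runif(1, 0.005, 0.03)
    dv <- runif(1, 2, 20)
    iop2 <- runif(1, 10, 25)
    opa <- iop2 * expm1(k * dv)
    expect_equal(friedenwaldRigidity(iop2, opa, dv), k,
                 tolerance = 1e-12)
  }
  expect_gt(friedenwaldRigidity(16, 5, 10), friedenwaldRigidity(16, 4, 10))
  expect_lt(friedenwaldRigidity(16, 4, 12), friedenwaldRigidity(16, 4, 10))
})

test_that("Corvis stiffness parameters", {
  expect_equal(stiffnessA1(100, 15, 0.6589), 129.00, tolerance = 1e-4)
  expect_equal(stiffnessA1(15, 15, 0.5), 0)
  expect_equal(stiffnessA1(100, 15, 0.33), 2 * stiffnessA1(100, 15, 0.66))
  expect_error(stiffnessA1(100, 15, 0), "deltaA1Mm")

  expect_equal(stiffnessHC(100, 15, 0.66, 6.24), 85 / 5.58)
  expect_equal(stiffnessHC(100, 15, 0.66, 6.24), 15.233, tolerance = 1e-3)
  expect_equal(stiffnessHC(15, 15, 0.66, 6.24), 0)
  expect_error(stiffnessHC(100, 15, 0.66, 0.66), "exceed")

  # SP-HC < SP-A1 whenever the concavity travel exceeds the applanation
  # deflection
  set.seed(2)
  for (i in 1:30) {
    dA1 <- runif(1, 0.3, 1)
    dHC <- dA1 + runif(1, dA1, 6)
    expect_lt(stiffnessHC(100, 15, dA1, dHC), stiffnessA1(100, 15, dA1))
  }
})

test_that("pressure-volume ratio", {
  expect_equal(pvRatio(16.95, 175.30), 0.09669, tolerance = 1e-4)
  expect_equal(pvRatio(0, 100), 0)
  expect_equal(pvRatio(3 * 16, 3 * 175), pvRatio(16, 175))
  expect_error(pvRatio(16, 0), "acvUl")
})

test_that("schematic-eye axial length: anchor, monotonicity, oracle", {
  eye <- schematicEyeConstants()
  expect_equal(axialLengthSchematicEye(0, eye$referenceRadiusMm),
               eye$emmetropicAlMm)

  alEmm <- axialLengthSchematicEye(0, 7.8)
  expect_gt(axialLengthSchematicEye(-3, 7.8), alEmm)  # myope longer
  expect_lt(axialLengthSchematicEye(3, 7.8), alEmm)   # hyperope shorter
  expect_lt(axialLengthSchematicEye(0, 7.3), alEmm)   # steeper: shorter

  # agrees with the independent image-chaining paraxial oracle
  for (se in c(-5, -2, 0, 1.5, 4)) for (r in c(7.3, 7.8, 8.2)) {
    expect_equal(axialLengthSchematicEye(se, r),
                 oracleAxialLength(se, r), tolerance = 1e-9)
  }
  expect_error(axialLengthSchematicEye(-8, 7.8), "6 D")
})

test_that("computeSubject composes the derived quantities", {
  rec <- data.frame(subject_id = "S1", iop_mmhg = 16, opa_mmhg = 4,
                    acv_ul = 170, al_mm = 24)
  out <- computeSubject(rec, deltaTUm = 5)
  expect_equal(out$dv_ul, 4 * pi * 12^2 * 0.005)
  expect_equal(out$dv_ul, 9.0478, tolerance = 1e-4)
  expect_equal(out$k_per_ul, log(1.25) / out$dv_ul)
  expect_equal(out$k_per_ul, 0.024662, tolerance = 1e-4)
  expect_equal(out$al_source, "measured")
  expect_true(is.na(out$sp_a1) && is.na(out$sp_hc))  # Corvis absent: no error
  expect_equal(out$pv_ratio_mmhg_per_ul, 16 / 170)

  # AL derived from the schematic eye when absent
  rec2 <- data.frame(iop_mmhg = 16, opa_mmhg = 4, acv_ul = 170,
                     refraction_se_d = -2, corneal_radius_mm = 7.8)
  out2 <- computeSubject(rec2, deltaTUm = 5)
  expect_equal(out2$al_source, "schematic_eye")
  expect_equal(out2$al_mm, axialLengthSchematicEye(-2, 7.8))

  expect_error(computeSubject(data.frame(opa_mmhg = 4), deltaTUm = 5),
               "iop_mmhg")
  expect_error(computeSubject(data.frame(iop_mmhg = 16, opa_mmhg = 4),
                              deltaTUm = 5), "al_mm")
})

test_that("cohort round-trip: recomputed k equals the generating k", {
  co <- simulateCohort(cohortSimParams(nSubjects = 40, seed = 9))
  out <- computeCohort(co)
  expect_equal(out$k_per_ul, out$k_true_per_ul, tolerance = 1e-9)
  expect_true(all(out$compute_error == ""))
  # exact model differs from thin shell only marginally at these scales
  outEx <- computeCohort(co, modelControl(volumeModel = "exact"))
  expect_equal(outEx$k_per_ul, out$k_per_ul, tolerance = 1e-2)
  expect_true(all(outEx$k_per_ul <= out$k_per_ul))
})
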