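test_that("Pearson correlation: hand-checked values and invariances", {
  expect_equal(pearsonCorr(1:3, c(2, 4, 6))$estimate, 1)
  expect_equal(pearsonCorr(1:4, c(1, 3, 2, 4))$estimate, 0.8)
  expect_equal(pearsonCorr(1:5, -(1:5))$estimate, -1)

  set.seed(1)
  x <- rnorm(30); y <- x + rnorm(30)
  r0 <- pearsonCorr(x, y)
  expect_equal(pearsonCorr(2 * x + 5, y)$estimate, r0$estimate)
  expect_equal(pearsonCorr(-x, y)$estimate, -r0$estimate)
  expect_equal(r0$p_value, cor.test(x, y)$p.value)

  expect_error(pearsonCorr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonCorr(1:2, 2:3), "3 complete pairs")
})

test_that("Mann-Whitney U: exact enumeration and tie handling", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1 / 3)
  expect_true(r$exact)

  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_false(same$exact)                  # ties: normal approximation

  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals the permutation oracle", {
  set.seed(7)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- rnorm(n1)
    y <- rnorm(n2, 0.5)
    got <- mannWhitneyU(x, y)$p_value
    expect_equal(got, permutationMannWhitneyP(x, y), tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("Shapiro-Wilk wrapper behaviour", {
  expect_equal(shapiroWilk(c(1, 2, 3))$statistic, 1, tolerance = 1e-6)
  set.seed(3)
  g <- shapiroWilk(rnorm(500))
  expect_gt(g$statistic, 0.99)
  # heavy tails are detected with high power
  set.seed(4)
  rej <- mean(replicate(50, shapiroWilk(rt(100, df = 1))$p_value < 0.05))
  expect_gt(rej, 0.9)
  expect_error(shapiroWilk(rep(2, 10)), "constant")
  expect_error(shapiroWilk(1:2), "between 3 and 2000")
})

test_that("paired t-test wrapper behaviour", {
  d <- c(1, -1, 2, -2, 0)
  r <- pairedT(d + 10, rep(10, 5))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)

  expect_error(pairedT(1:5, 1:5), "zero variance")
  expect_error(pairedT(1:5 + 3, 1:5), "zero variance")  # constant shift
  expect_error(pairedT(1, 2), "2 complete pairs")
})

test_that("Bland-Altman bias and limits of agreement", {
  r <- blandAltman(c(10, 20, 30), c(12, 19, 33))
  expect_equal(r$estimate, -4 / 3, tolerance = 1e-10)
  expect_equal(unname(r$loa), c(-5.413, 2.747), tolerance = 1e-3)

  same <- blandAltman(1:5, 1:5)
  expect_equal(same$estimate, 0)
  expect_equal(unname(same$loa), c(0, 0))

  set.seed(5)
  x <- rnorm(10000); y <- x + rnorm(10000, 0, 0.5)
  ba <- blandAltman(x, y)
  inside <- mean(ba$diffs >= ba$loa["lower"] & ba$diffs <= ba$loa["upper"])
  expect_gte(inside, 0.94)
  expect_lte(inside, 0.96)
})

test_that("report assembly: recovery, strata and per-cell n", {
  co <- simulateCohort(cohortSimParams(nSubjects = 500, seed = 21))
  tab <- computeCohort(co)
  rep <- buildReport(tab)
  corr <- rep$correlations
  alRow <- corr[corr$stratum == "combined" & corr$variable == "al_mm", ]
  expect_equal(alRow$r, -0.53, tolerance = 0.2)
  expect_true(abs(alRow$r + 0.53) < 0.08)
  expect_true(alRow$significant)
  expect_true(all(c("combined", "control_only") %in% corr$stratum))
  expect_true(all(corr$n <= 500))

  # missing Corvis fields reduce per-cell n without dropping the row
  tab2 <- tab
  tab2$sp_a1[1:100] <- NA
  rep2 <- buildReport(tab2)
  spRow <- rep2$correlations[rep2$correlations$stratum == "combined" &
                               rep2$correlations$variable == "sp_a1", ]
  expect_equal(spRow$n, 400)

  gs <- rep$groupSummary
  expect_true(all(c("mean_control", "sd_control", "n_control",
                    "p_value") %in% names(gs)))

  # single-group cohort: comparison columns omitted, correlations kept
  one <- buildReport(tab[tab$group == "control", ])
  expect_false("p_value" %in% names(one$groupSummary))
  expect_gt(nrow(one$correlations), 0)

  expect_error(buildReport(tab[0, ]), "empty")
})

test_that("report output is deterministic and writable", {
  co <- simulateCohort(cohortSimParams(nSubjects = 40, seed = 2))
  tab <- computeCohort(co)
  r1 <- buildReport(tab)
  r2 <- buildReport(tab)
  expect_identical(r1, r2)

  d <- withr::local_tempdir()
  paths <- writeReport(r1, d)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(d, "correlations.csv"))
  expect_equal(back$r, r1$correlations$r, tolerance = 1e-12)
})
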