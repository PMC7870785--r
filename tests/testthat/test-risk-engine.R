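p2 <- table2Params()

test_that("LR is 1 when affected and unaffected parameters coincide", {
  set.seed(41)
  x <- matrix(rnorm(40, 0, 0.4), 10, 4)
  expect_equal(likelihoodRatio(x, p2$control, p2$control), rep(1, 10),
               tolerance = 1e-12)
  expect_equal(likelihoodRatio(x, p2$control, p2$control,
                               useCorrelations = TRUE),
               rep(1, 10), tolerance = 1e-12)
})

test_that("univariate LR matches direct normal-density evaluation", {
  # sHLA-G at the control mean, trisomy-18 vs control parameters
  lr <- likelihoodRatio(0.0455, p2$T18, p2$control, markers = "shla_g")
  expect_equal(lr, dnorm(0.0455, -0.3269, 0.21661) /
                 dnorm(0.0455, 0.0455, 0.22564), tolerance = 1e-12)
  expect_equal(lr, 0.2376, tolerance = 0.0005 / 0.2376)
})

test_that("equal-SD LR at the affected mean has the closed form", {
  s <- 0.2; delta <- 0.37
  aff <- groupParams("T18", mean = rep(-delta, 4), sd = rep(s, 4))
  una <- groupParams("control", mean = rep(0, 4), sd = rep(s, 4))
  lr <- likelihoodRatio(rep(-delta, 4)[1], aff, una, markers = "afp")
  expect_equal(lr, exp(delta^2 / (2 * s^2)), tolerance = 1e-12)
})

test_that("multivariate LR agrees with a solve()-based density oracle", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(4, 0, 0.4)
    lr <- likelihoodRatio(x, p2$T18, p2$control, useCorrelations = TRUE)
    oracle <- denseMvn(x, groupMean(p2$T18), groupCovariance(p2$T18)) /
      denseMvn(x, groupMean(p2$control), groupCovariance(p2$control))
    expect_equal(lr, oracle, tolerance = 1e-10)
  }
})

test_that("uncorrelated and correlated LR coincide for diagonal models", {
  aff <- groupParams("T18", mean = c(-0.2, -0.6, -0.35, -0.33),
                     sd = c(0.25, 0.52, 0.28, 0.22))
  una <- groupParams("control", mean = c(0, 0.06, -0.02, 0.05),
                     sd = c(0.16, 0.4, 0.17, 0.23))
  set.seed(43)
  x <- matrix(rnorm(40, 0, 0.4), 10, 4)
  expect_equal(likelihoodRatio(x, aff, una),
               likelihoodRatio(x, aff, una, useCorrelations = TRUE),
               tolerance = 1e-12)
})

test_that("LR is translation-equivariant in the marker means", {
  x <- c(-0.1, -0.4, -0.2, -0.3)
  shift <- c(0.2, 0, 0, 0)
  aff <- p2$T18; una <- p2$control
  aff2 <- groupParams("T18", groupMean(aff) + shift, groupSD(aff),
                      groupCorrelation(aff))
  una2 <- groupParams("control", groupMean(una) + shift, groupSD(una),
                      groupCorrelation(una))
  expect_equal(likelihoodRatio(x + shift, aff2, una2),
               likelihoodRatio(x, aff, una), tolerance = 1e-12)
})

test_that("posterior risk follows the odds form and its fixed points", {
  expect_equal(posteriorRisk(0.5, 1), 0.5)
  expect_equal(posteriorRisk(1 / 100, 99), 0.5)
  expect_equal(posteriorRisk(1 / 5000, 171), 0.0331, tolerance = 2e-3)
  expect_error(posteriorRisk(0, 2), "prior")
  expect_error(posteriorRisk(1.2, 2), "prior")
  expect_error(posteriorRisk(0.5, -1), "positive")
  # strictly increasing in LR, equal to prior at LR = 1
  lrs <- c(0.1, 0.5, 1, 2, 10, 171)
  post <- posteriorRisk(0.01, lrs)
  expect_true(all(diff(post) > 0))
  expect_equal(posteriorRisk(0.01, 1), 0.01)
})

test_that("scoreCohort produces one row per subject per trisomy", {
  coh <- computeMoM(generateCohort(smallConfig(seed = 44, nCtrl = 40)))
  res <- scoreCohort(coh, paramsByGroup = p2)
  expect_equal(nrow(res), 2 * ncol(coh))
  expect_setequal(unique(res$trisomy), c("T21", "T18"))
  expect_true(all(res$lr > 0))
  expect_true(all(res$posterior > 0 & res$posterior < 1))
  expect_equal(res$posterior,
               posteriorRisk(res$prior, res$lr), tolerance = 1e-12)
  # threshold extremes
  all_pos <- scoreCohort(coh, paramsByGroup = p2, threshold = 0)
  expect_true(all(all_pos$screen_positive))
  none <- scoreCohort(coh, paramsByGroup = p2, threshold = 1)
  expect_false(any(none$screen_positive))
})

test_that("targetFpr mode keeps the control positive rate at or below target", {
  coh <- computeMoM(generateCohort(simulationConfig(
    groupSizes = c(control = 400, T21 = 40, T18 = 40), seed = 45)))
  res <- scoreCohort(coh, paramsByGroup = p2, trisomies = "T18",
                     targetFpr = 0.05)
  fpr <- mean(res$screen_positive[res$group == "control"])
  expect_lte(fpr, 0.05)
  expect_gt(fpr, 0.02)  # cutoff is placed, not degenerate
  sens <- mean(res$screen_positive[res$group == "T18"])
  expect_gt(sens, 0.5)
})

test_that("LR-based ranking beats single markers at a fixed FPR", {
  # Neyman-Pearson: on model-generated data the four-marker LR dominates
  # any one marker's detection rate at 5 percent FPR (within noise)
  cfg <- simulationConfig(groupSizes = c(control = 20000, T21 = 0,
                                         T18 = 20000), seed = 46)
  coh <- computeMoM(generateCohort(cfg))
  grp <- as.character(subjectGroups(coh))
  labs <- as.integer(grp == "T18")
  res <- scoreCohort(coh, paramsByGroup = p2, trisomies = "T18")
  dr_lr <- detectionRateAtFPR(res$posterior, labs, 0.05,
                              direction = "higher_is_positive")$detection_rate
  lmom <- log10MoM(coh)
  for (mk in screeningMarkers()) {
    dr_mk <- detectionRateAtFPR(lmom[mk, ], labs, 0.05)$detection_rate
    expect_gt(dr_lr, dr_mk - 0.01)
  }
  # and the posterior's ROC dominates each single marker's AUC
  auc_lr <- aucValue(rocCurve(res$posterior, labs,
                              direction = "higher_is_positive"))
  for (mk in screeningMarkers()) {
    expect_gt(auc_lr, aucValue(rocCurve(lmom[mk, ], labs)) - 0.005)
  }
})

test_that("flat and age-table priors are looked up correctly", {
  pm <- priorModel()
  expect_equal(priorProbability(pm, "T18"), 1 / 5000)
  expect_equal(priorProbability(pm, "T21"), 1 / 700)
  at <- data.frame(age = c(20, 30, 40), T21 = c(1e-4, 5e-4, 5e-3),
                   T18 = c(2e-5, 1e-4, 1e-3))
  pma <- priorModel(ageTable = at)
  expect_equal(priorProbability(pma, "T21", c(19, 31, 44)),
               c(1e-4, 5e-4, 5e-3))
  expect_error(priorModel(T18 = 0), "prior")
})
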