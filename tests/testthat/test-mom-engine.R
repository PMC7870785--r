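test_that("fitMedianCurve matches a sort-based median oracle per week", {
  set.seed(21)
  n <- 5 * 5  # five handcrafted controls per week
  week <- rep(15:19, each = 5)
  lv <- rbind(afp = runif(n, 20, 60), free_bhcg = runif(n, 5, 40),
              ue3 = runif(n, 2, 9), shla_g = runif(n, 50, 200))
  coh <- ScreeningCohort(lv, group = rep("control", n),
                         age = runif(n, 18, 35), weight = runif(n, 40, 90),
                         gestationalWeek = week)
  curve <- fitMedianCurve(coh)
  oracle <- function(x) sort(x)[ceiling(length(x) / 2)]
  for (wk in 15:19) {
    for (mk in c("afp", "free_bhcg", "ue3")) {
      expect_equal(medianLevel(curve, mk, wk), oracle(lv[mk, week == wk]))
    }
  }
  expect_equal(medianLevel(curve, "shla_g"), oracle(lv["shla_g", ]))
  expect_true(isFlatMedian(curve, "shla_g"))
  expect_false(isFlatMedian(curve, "afp"))
})

test_that("a single control becomes its own median with MoM 1", {
  lv <- matrix(c(33, 21, 4.4, 99), 4,
               dimnames = list(screeningMarkers(), NULL))
  coh <- ScreeningCohort(lv, group = "control", age = 30, weight = 55,
                         gestationalWeek = 16L)
  coh <- computeMoM(coh, fitMedianCurve(coh))
  expect_equal(unname(momValues(coh)[, 1]), rep(1, 4))
  expect_equal(unname(log10MoM(coh)[, 1]), rep(0, 4))
})

test_that("missing week strata are reported", {
  lv <- matrix(rep(c(33, 21, 4.4, 99), 3), 4,
               dimnames = list(screeningMarkers(), NULL))
  coh <- ScreeningCohort(lv, group = rep("control", 3), age = rep(30, 3),
                         weight = rep(55, 3), gestationalWeek = c(15L, 15L, 16L))
  expect_error(fitMedianCurve(coh, weeks = 15:19), "17")
})

test_that("control median MoM is exactly 1 in every stratum by construction", {
  coh <- generateCohort(simulationConfig(
    groupSizes = c(control = 157, T21 = 0, T18 = 0), seed = 12))
  coh <- computeMoM(coh, fitMedianCurve(coh))
  mom <- momValues(coh); wk <- gestationalWeeks(coh)
  lower_med <- function(x) sort(x)[ceiling(length(x) / 2)]
  for (w in unique(wk)) {
    for (mk in c("afp", "free_bhcg", "ue3")) {
      expect_equal(unname(lower_med(mom[mk, wk == w])), 1)
    }
  }
  expect_equal(unname(lower_med(mom["shla_g", ])), 1)
})

test_that("published median levels give the published MoM values", {
  curve <- flatCurve()
  m18 <- momFromLevels(c(afp = 30, free_bhcg = 20, ue3 = 4, shla_g = 47.8),
                       curve, 16)
  expect_equal(unname(m18$mom["shla_g"]), 0.4497, tolerance = 1e-4)
  m21 <- momFromLevels(c(afp = 30, free_bhcg = 20, ue3 = 4, shla_g = 125.7),
                       curve, 16)
  expect_equal(unname(m21$mom["shla_g"]), 1.1825, tolerance = 1e-4)
  expect_equal(unname(m18$log10_mom["shla_g"]), log10(0.4497),
               tolerance = 1e-4)
})

test_that("MoM is scale-invariant and rank-preserving within a stratum", {
  set.seed(33)
  lv <- rbind(afp = runif(10, 20, 60), free_bhcg = runif(10, 5, 40),
              ue3 = runif(10, 2, 9), shla_g = runif(10, 50, 200))
  curve1 <- flatCurve()
  curve2 <- flatCurve(afp = 3 * 30)
  lv2 <- lv
  lv2["afp", ] <- 3 * lv["afp", ]
  m1 <- momFromLevels(lv, curve1, 16)
  m2 <- momFromLevels(lv2, curve2, 16)
  expect_equal(m1$mom["afp", ], m2$mom["afp", ], tolerance = 1e-12)
  expect_identical(order(lv["shla_g", ]), order(m1$mom["shla_g", ]))
  expect_identical(order(lv["shla_g", ]), order(m1$log10_mom["shla_g", ]))
})

test_that("non-positive levels are rejected with subject context", {
  lv <- matrix(c(33, 21, 4.4, 99, 30, -1, 4, 100), 4,
               dimnames = list(screeningMarkers(), c("A", "B")))
  expect_error(momFromLevels(lv, flatCurve(), 16), "free_bhcg.*B")
})

test_that("identity weight model leaves MoM untouched", {
  coh <- computeMoM(generateCohort(smallConfig(seed = 9)))
  adj <- weightAdjust(coh, weightModel())
  expect_identical(momValues(coh), momValues(adj))
  expect_false(S4Vectors::metadata(adj)$weight_adjusted)
})

test_that("a known expected-MoM factor cancels exactly", {
  mom <- matrix(1.1, 1, 4)
  coh <- cohortFromMoM(mom, weight = 70)
  model <- structure(list(
    type = "reciprocal",
    coefficients = matrix(c(rep(1.1, 4), rep(0, 4)), ncol = 2,
                          dimnames = list(screeningMarkers(),
                                          c("intercept", "inv_weight")))),
    class = "WeightModel")
  adj <- weightAdjust(coh, model)
  expect_equal(unname(momValues(adj)[, 1]), rep(1, 4), tolerance = 1e-12)
  expect_true(S4Vectors::metadata(adj)$weight_adjusted)
})

test_that("reciprocal adjustment flattens a built-in weight trend", {
  set.seed(77)
  n <- 20000
  w <- runif(n, 40, 90)
  expected <- 0.5 + 30 / w            # decreasing in weight
  mom <- sapply(1:4, function(j) expected * rlnorm(n, 0, 0.08))
  coh <- cohortFromMoM(mom, weight = w)
  fit <- fitWeightModel(coh)
  adj <- weightAdjust(coh, fit)
  dec <- cut(w, quantile(w, 0:10 / 10), include.lowest = TRUE)
  med_by_dec <- tapply(momValues(adj)["shla_g", ], dec, median)
  expect_true(all(abs(med_by_dec - 1) < 0.02))
})

test_that("weight adjustment rejects non-positive weights", {
  expect_error(expectedMoM(weightModel(), c(60, 0)), "weight")
})
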