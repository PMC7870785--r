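test_that("empirical AUC matches brute-force pair counting", {
  r <- rocCurve(c(1, 2, 3, 4), c(0, 1, 0, 1),
                direction = "higher_is_positive")
  expect_equal(aucValue(r), 0.75)
  expect_equal(aucValue(r), bruteAUC(c(1, 2, 3, 4), c(0, 1, 0, 1)))
  sep <- rocCurve(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(aucValue(sep), 1.0)
  set.seed(51)
  s <- rnorm(10000); l <- sample(0:1, 10000, replace = TRUE)
  expect_lt(abs(aucValue(rocCurve(s, l, "higher_is_positive")) - 0.5), 0.02)
})

test_that("AUC equals the Mann-Whitney win fraction exactly, with ties", {
  set.seed(52)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    s <- c(sample(1:6, n1, TRUE), sample(1:6, n0, TRUE))  # heavy ties
    l <- rep(1:0, c(n1, n0))
    auc <- aucValue(rocCurve(s, l, direction = "higher_is_positive"))
    expect_equal(auc * n1 * n0, bruteU(s[l == 1], s[l == 0]))
  }
})

test_that("flipping direction maps AUC to its complement", {
  set.seed(53)
  s <- rnorm(60); l <- rep(0:1, 30)
  a_hi <- aucValue(rocCurve(s, l, "higher_is_positive"))
  a_lo <- aucValue(rocCurve(s, l, "lower_is_positive"))
  expect_equal(a_hi + a_lo, 1)
})

test_that("ROC points are monotone and DeLong CI brackets the AUC", {
  set.seed(54)
  s <- c(rnorm(80), rnorm(60, 1)); l <- rep(0:1, c(80, 60))
  r <- rocCurve(s, l)
  pts <- rocPoints(r)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_lte(r@ciLow, aucValue(r))
  expect_gte(r@ciHigh, aucValue(r))
  expect_lt(r@pValue, 0.01)
  expect_error(rocCurve(s, rep(1, 140)), "both classes")
})

test_that("Youden cutoff equals exhaustive search on random instances", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    n1 <- sample(5:(n - 5), 1)
    s <- round(c(rnorm(n1, 0.8), rnorm(n - n1)), 2)
    l <- rep(1:0, c(n1, n - n1))
    r <- rocCurve(s, l, direction = "higher_is_positive")
    got <- youdenCutoff(r)
    want <- bruteYouden(s, l)
    expect_equal(got@youden, want$j, tolerance = 1e-12)
    expect_equal(got@cutoff, want$cut, tolerance = 1e-9)
    expect_equal(got@sensitivity, want$sens)
    expect_equal(got@specificity, want$spec)
  }
})

test_that("Youden point on separated data reaches J = 1 at the midpoint", {
  r <- rocCurve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  y <- youdenCutoff(r)
  expect_equal(y@youden, 1)
  expect_equal(y@cutoff, 6.5)
  expect_equal(unname(confusionCounts(y)), c(3L, 0L, 0L, 3L))
})

test_that("empirical Youden cutoff approaches the two-Gaussian crossing", {
  p <- table2Params()
  m1 <- groupMean(p$T18)["shla_g"]; s1 <- groupSD(p$T18)["shla_g"]
  m0 <- groupMean(p$control)["shla_g"]; s0 <- groupSD(p$control)["shla_g"]
  # closed-form crossing of the two class densities between the means
  cross <- uniroot(function(x) dnorm(x, m1, s1) - dnorm(x, m0, s0),
                   c(m1, m0))$root
  set.seed(56)
  x <- c(rnorm(100000, m1, s1), rnorm(100000, m0, s0))
  l <- rep(1:0, each = 100000)
  y <- youdenCutoff(rocCurve(x, l, direction = "lower_is_positive"))
  expect_lt(abs(y@cutoff - cross), 0.02)
})

test_that("metrics from published rates reproduce the predictive values", {
  m <- metricsFromRates(0.855, 0.887, 83, 797)
  expect_equal(unname(confusionCounts(m)),
               c(71L, 90L, 12L, 707L))  # tp, fp, fn, tn
  expect_equal(ppvValue(m), 0.441, tolerance = 5e-4 / 0.441)
  expect_equal(npvValue(m), 0.983, tolerance = 5e-4 / 0.983)
  expect_equal(plrValue(m), 7.58, tolerance = 5e-3 / 7.58)
  expect_equal(nlrValue(m), 0.16, tolerance = 5e-3 / 0.16)
  # trivial operating points
  perfect <- metricsFromRates(1, 1, 10, 20)
  expect_equal(ppvValue(perfect), 1)
  expect_equal(npvValue(perfect), 1)
  expect_equal(nlrValue(perfect), 0)
  coin <- metricsFromRates(0.5, 0.5, 100, 100)
  expect_equal(ppvValue(coin), 0.5)
  expect_equal(npvValue(coin), 0.5)
  expect_equal(plrValue(coin), 1)
  expect_equal(nlrValue(coin), 1)
  expect_error(metricsFromRates(1.2, 0.5, 10, 10), "rates")
})

test_that("rates survive the counts round trip within half a count", {
  set.seed(57)
  for (i in 1:25) {
    nCase <- sample(20:300, 1); nCtrl <- sample(20:900, 1)
    sens <- runif(1); spec <- runif(1)
    m <- metricsFromRates(sens, spec, nCase, nCtrl)
    tol <- 1 / (2 * min(nCase, nCtrl))
    expect_lte(abs(sensitivityValue(m) - sens), tol)
    expect_lte(abs(specificityValue(m) - spec), tol)
  }
})

test_that("detection rate at fixed FPR honors the step-function convention", {
  # null case: cases distributed as controls -> detection ~ target FPR
  set.seed(58)
  s <- rnorm(50000); l <- rep(0:1, 25000)
  dr <- detectionRateAtFPR(s, l, 0.05, direction = "higher_is_positive")
  expect_lt(abs(dr$detection_rate - 0.05), 0.01)
  expect_lte(dr$achieved_fpr, 0.05)
  # separated case: everything detected
  s2 <- c(rnorm(500), rnorm(100, 10)); l2 <- rep(0:1, c(500, 100))
  expect_equal(detectionRateAtFPR(s2, l2, 0.05)$detection_rate, 1)
  expect_error(detectionRateAtFPR(rnorm(10), rep(0:1, 5), 0.05),
               "too few controls")
})

test_that("logistic fit recovers a known coefficient", {
  set.seed(59)
  n <- 20000
  x <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + 1.5 * x[, "signal"]))
  fit <- logisticFit(x, y)
  expect_true(fit@converged)
  tab <- coefficientTable(fit)
  expect_equal(tab$coefficient[tab$term == "signal"], 1.5, tolerance = 0.05)
  expect_equal(tab$exp_b, exp(tab$coefficient))
  expect_true(all(tab$ci_low < tab$exp_b & tab$exp_b < tab$ci_high))
  noise_row <- tab[tab$term == "noise", ]
  expect_true(noise_row$ci_low < 1 && noise_row$ci_high > 1)
})

test_that("perfect separation is flagged and reported unconverged", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
              dimnames = list(NULL, "v"))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- suppressWarnings(logisticFit(data.frame(v = rep(x, 3)),
                                      rep(y, 3)))
  expect_true(fit@separation)
  expect_false(fit@converged)
})

test_that("degenerate design matrices are rejected", {
  x <- cbind(a = rnorm(50), b = rep(2, 50))
  y <- rbinom(50, 1, 0.5)
  expect_error(logisticFit(x, y), "constant")
  expect_error(logisticFit(matrix(rnorm(12), 4, 3), c(0, 1, 0, 1)),
               "more observations")
})
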