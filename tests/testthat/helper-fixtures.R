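# Shared fixtures, built in code.

# flat median curve: every marker week-independent, convenient for
# handcrafted cohorts
flatCurve <- function(afp = 30, free_bhcg = 20, ue3 = 4, shla_g = 106.3) {
  medianCurve(list(afp = afp, free_bhcg = free_bhcg, ue3 = ue3,
                   shla_g = shla_g))
}

# a tiny cohort from explicit MoM vectors (rows of `mom`), via a flat curve
cohortFromMoM <- function(mom, group = "control", week = 16L,
                          age = 28, weight = 54.5) {
  curve <- flatCurve()
  med <- c(afp = 30, free_bhcg = 20, ue3 = 4, shla_g = 106.3)
  lv <- t(mom) * med
  coh <- ScreeningCohort(lv, group = rep_len(group, ncol(lv)),
                         age = rep_len(age, ncol(lv)),
                         weight = rep_len(weight, ncol(lv)),
                         gestationalWeek = rep_len(week, ncol(lv)))
  computeMoM(coh, curve)
}

smallConfig <- function(seed = 1L, nCtrl = 60L, nT21 = 15L, nT18 = 15L) {
  simulationConfig(groupSizes = c(control = nCtrl, T21 = nT21, T18 = nT18),
                   seed = seed)
}

# brute-force AUC: (wins + half ties) over all case-control pairs,
# higher score = positive
bruteAUC <- function(scores, labels) {
  ca <- scores[labels == 1]; co <- scores[labels == 0]
  tot <- 0
  for (x in ca) tot <- tot + sum(x > co) + 0.5 * sum(x == co)
  tot / (length(ca) * length(co))
}

# brute-force Mann-Whitney U of a vs b (pairs where a wins, half for ties)
bruteU <- function(a, b) {
  tot <- 0
  for (x in a) tot <- tot + sum(x > b) + 0.5 * sum(x == b)
  tot
}

# exhaustive Youden search over midpoint cutoffs; higher score = positive
bruteYouden <- function(scores, labels, lower = FALSE) {
  s <- if (lower) -scores else scores
  u <- sort(unique(s))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (ct in cuts) {
    pos <- s > ct
    sens <- sum(pos & labels == 1) / sum(labels == 1)
    spec <- sum(!pos & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens)) {
      best <- list(cut = ct, j = j, sens = sens, spec = spec)
    }
  }
  if (lower) best$cut <- -best$cut
  best
}

# direct (solve-based) multivariate normal density, independent of the
# Cholesky path used by likelihoodRatio
denseMvn <- function(x, mean, sigma) {
  d <- length(mean)
  q <- as.numeric(t(x - mean) %*% solve(sigma) %*% (x - mean))
  exp(-q / 2) / sqrt((2 * pi)^d * det(sigma))
}
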