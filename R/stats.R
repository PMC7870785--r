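#' Summarize one group's MoM distribution
#'
#' Computes, per marker, the median MoM, the arithmetic mean and sample SD
#' (n-1 denominator) of log10 MoM, and the pairwise Pearson correlation
#' matrix of log10 MoM -- the parameter block that drives the Gaussian risk
#' model. A marker with zero variance yields SD 0 and missing (NA)
#' correlations in its row/column.
#'
#' @param cohort A \linkS4class{ScreeningCohort} with MoM assays
#'   (\code{\link{computeMoM}}).
#' @param group Which group to summarize ("control", "T21" or "T18").
#' @return A \linkS4class{GroupParams}.
#' @examples
#' coh <- computeMoM(generateCohort(simulationConfig(
#'   groupSizes = c(control = 200, T21 = 0, T18 = 50), seed = 3)))
#' summarizeGroup(coh, "T18")
#' @export
summarizeGroup <- function(cohort, group) {
  sel <- subjectGroups(cohort) == group
  n <- sum(sel)
  if (n < 2) stop("need at least 2 subjects in group '", group, "' (got ", n, ")")
  lm <- log10MoM(cohort)[, sel, drop = FALSE]
  mom <- momValues(cohort)[, sel, drop = FALSE]
  mu <- rowMeans(lm)
  sdv <- apply(lm, 1, stats::sd)
  med <- apply(mom, 1, stats::median)
  R <- suppressWarnings(stats::cor(t(lm)))  # zero-variance rows -> NA
  diag(R) <- 1
  groupParams(group, mean = mu, sd = sdv, correlation = R,
              medianMoM = med, n = n)
}

#' Mann-Whitney U comparison of two samples
#'
#' Rank-sum comparison with midrank tie handling. The reported U counts the
#' pairs in which a value from \code{a} exceeds one from \code{b} (ties
#' contributing 1/2), so \code{U / (n_a n_b)} is the empirical AUC of
#' \code{a} vs \code{b}. The two-sided p-value is exact (network algorithm)
#' when both samples are tie-free and \code{n_a * n_b <= exact_limit},
#' otherwise a normal approximation with continuity and tie correction is
#' used.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exactLimit Largest \code{n_a * n_b} for which the exact p-value is
#'   attempted (default 10000).
#' @return A list of class \code{"MWTest"}: \code{U}, \code{p_value},
#'   \code{n_a}, \code{n_b}, \code{method}.
#' @examples
#' mannWhitney(c(1, 3, 5), c(2, 4, 6))$U   # 3 of 9 pairs won by 'a'...
#' @export
mannWhitney <- function(a, b, exactLimit = 10000) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) * length(b) <= exactLimit
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  structure(list(U = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(a), n_b = length(b),
                 method = if (exact) "exact" else "normal approximation"),
            class = "MWTest")
}

#' @export
print.MWTest <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d vs %d), p = %.4g [%s]\n",
              x$U, x$n_a, x$n_b, x$p_value, x$method))
  invisible(x)
}

#' Pairwise marker correlations within a group
#'
#' Bivariate correlation of all marker pairs on the log10 MoM scale (Pearson
#' by default, matching the Gaussian risk model's scale; Spearman available),
#' with two-sided p-values from the t-distribution with n-2 degrees of
#' freedom. Zero-variance markers give NA rows/columns.
#'
#' @param cohort A \linkS4class{ScreeningCohort} with MoM assays.
#' @param group Group to analyze.
#' @param method "pearson" (default) or "spearman".
#' @return List with \code{r} and \code{p} 4x4 matrices and \code{n}.
#' @export
pairwiseCorrelations <- function(cohort, group,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  sel <- subjectGroups(cohort) == group
  n <- sum(sel)
  if (n < 3) stop("need at least 3 subjects for correlations")
  lm <- t(log10MoM(cohort)[, sel, drop = FALSE])
  r <- suppressWarnings(stats::cor(lm, method = method))
  diag(r) <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Group summary table (medians, log10 MoM moments, correlations)
#'
#' Builds the standard distribution report for a screened cohort: one column
#' per group with median MoM, mean and SD log10 MoM per marker, followed by
#' the pairwise correlation block, plus Mann-Whitney comparisons of each
#' trisomy group against controls per marker.
#'
#' @param cohort A \linkS4class{ScreeningCohort} with MoM assays.
#' @param groups Groups to include (default: those present with n >= 2).
#' @return List with \code{distribution} (data.frame), \code{correlations}
#'   (data.frame, one row per pair per group) and \code{tests} (data.frame of
#'   Mann-Whitney results vs control).
#' @export
groupSummaryTable <- function(cohort, groups = NULL) {
  tab <- table(subjectGroups(cohort))
  if (is.null(groups))
    groups <- intersect(screeningGroups(), names(tab[tab >= 2]))
  params <- lapply(groups, function(g) summarizeGroup(cohort, g))
  names(params) <- groups
  mk <- screeningMarkers()
  lab <- markerLabels()
  dist <- do.call(rbind, lapply(groups, function(g) {
    p <- params[[g]]
    data.frame(group = g, n = p@n, marker = unname(lab[mk]),
               median_mom = unname(p@medianMoM),
               mean_log10_mom = unname(p@mean),
               sd_log10_mom = unname(p@sd), row.names = NULL)
  }))
  pairs <- utils::combn(mk, 2)
  corr <- do.call(rbind, lapply(groups, function(g) {
    pc <- pairwiseCorrelations(cohort, g)
    data.frame(group = g,
               marker_a = unname(lab[pairs[1, ]]),
               marker_b = unname(lab[pairs[2, ]]),
               r = pc$r[cbind(pairs[1, ], pairs[2, ])],
               p_value = pc$p[cbind(pairs[1, ], pairs[2, ])],
               row.names = NULL)
  }))
  tests <- NULL
  if ("control" %in% groups) {
    mom <- momValues(cohort)
    grp <- subjectGroups(cohort)
    tests <- do.call(rbind, lapply(setdiff(groups, "control"), function(g) {
      do.call(rbind, lapply(mk, function(m) {
        mw <- mannWhitney(mom[m, grp == g], mom[m, grp == "control"])
        data.frame(group = g, marker = unname(lab[m]), U = mw$U,
                   p_value = mw$p_value, row.names = NULL)
      }))
    }))
  }
  list(distribution = dist, correlations = corr, tests = tests)
}
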