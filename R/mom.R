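#' Fit control medians from a cohort
#'
#' Estimates the MoM denominator from the unaffected pregnancies of a cohort:
#' per-gestational-week medians for AFP, free beta-hCG and uE3 (each marker
#' normalized against its "appropriate gestational control group") and a
#' single overall median for sHLA-G, which is not gestation-dependent. By
#' construction the fitting controls then have median MoM exactly 1 in each
#' week stratum (week-indexed markers) and overall (sHLA-G).
#'
#' The median uses the lower-middle convention for even n (the lower of the
#' two central order statistics), so fitted medians are always observed
#' values and MoMs are bit-reproducible.
#'
#' @param cohort A \linkS4class{ScreeningCohort}; only its control subjects
#'   are used (or pass a cohort that is all controls).
#' @param weeks Integer weeks that must be covered (default 15:19, restricted
#'   to the weeks present when all controls fall in fewer weeks).
#' @return A \linkS4class{MedianCurve}.
#' @examples
#' coh <- generateCohort(simulationConfig(
#'   groupSizes = c(control = 100, T21 = 0, T18 = 0), seed = 1))
#' fitMedianCurve(coh)
#' @export
fitMedianCurve <- function(cohort, weeks = NULL) {
  ctrl <- cohort[, subjectGroups(cohort) == "control"]
  if (ncol(ctrl) == 0) stop("no control subjects to fit medians from")
  lv <- markerLevels(ctrl)
  wk <- gestationalWeeks(ctrl)
  if (is.null(weeks)) weeks <- sort(unique(wk))
  missing <- setdiff(weeks, unique(wk))
  if (length(missing))
    stop("no controls in gestational week(s): ",
         paste(missing, collapse = ", "))
  med <- list()
  for (mk in screeningMarkers()) {
    if (mk == "shla_g") {
      med[[mk]] <- lowerMedian(lv[mk, ])
    } else {
      v <- vapply(weeks, function(w) lowerMedian(lv[mk, wk == w]), numeric(1))
      names(v) <- as.character(weeks)
      med[[mk]] <- v
    }
  }
  medianCurve(med)
}

#' Lower-middle sample median
#'
#' For odd n the usual middle order statistic; for even n the lower of the
#' two central order statistics, so the median is always an observed value.
#'
#' @param x Numeric vector.
#' @return Scalar median.
#' @export
lowerMedian <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' MoM and log10 MoM for a vector of marker levels
#'
#' mom = level / median(marker, week); log10_mom = log10(mom). The low-level
#' kernel behind \code{\link{computeMoM}}; exact inverse of
#' \code{\link{reconstructLevels}}.
#'
#' @param levels Named numeric 4-vector (or markers x n matrix) of strictly
#'   positive concentrations.
#' @param curve A \linkS4class{MedianCurve}.
#' @param week Integer gestational week (scalar, or one per column).
#' @return For a vector input, a list with \code{mom} and \code{log10_mom}
#'   named 4-vectors; for a matrix input, a list of two matching matrices.
#' @examples
#' momFromLevels(c(afp = 30, free_bhcg = 20, ue3 = 4, shla_g = 47.8),
#'               defaultMedianCurve(), 15)$mom["shla_g"]   # 0.4497
#' @export
momFromLevels <- function(levels, curve, week) {
  if (is.matrix(levels)) {
    if (any(levels <= 0)) {
      bad <- which(levels <= 0, arr.ind = TRUE)[1, ]
      stop("non-positive level for marker '", rownames(levels)[bad[1]],
           "' in subject '", colnames(levels)[bad[2]], "'")
    }
    week <- rep_len(week, ncol(levels))
    uw <- unique(week)
    medByWeek <- vapply(uw, function(w) .mediansAt(curve, w), numeric(4))
    med <- medByWeek[, match(week, uw), drop = FALSE]
    mom <- levels / med
    return(list(mom = mom, log10_mom = log10(mom)))
  }
  if (any(levels <= 0))
    stop("non-positive level for marker '",
         screeningMarkers()[which(levels <= 0)[1]], "'")
  mom <- as.numeric(levels) / .mediansAt(curve, week)
  names(mom) <- screeningMarkers()
  list(mom = mom, log10_mom = log10(mom))
}

#' Add MoM assays to a cohort
#'
#' Normalizes every subject's marker levels to multiples of the median
#' against a control median curve, adding \code{"mom"} and \code{"log10_mom"}
#' assays.
#'
#' @param cohort A \linkS4class{ScreeningCohort}.
#' @param curve A \linkS4class{MedianCurve}; default: the curve stored by
#'   \code{\link{generateCohort}} in \code{metadata()}, else fitted from the
#'   cohort's controls via \code{\link{fitMedianCurve}}.
#' @return The cohort with MoM assays; \code{metadata()$weight_adjusted} is
#'   set to FALSE (see \code{\link{weightAdjust}}).
#' @examples
#' coh <- generateCohort(simulationConfig(
#'   groupSizes = c(control = 50, T21 = 0, T18 = 10), seed = 2))
#' coh <- computeMoM(coh)
#' momValues(coh)[, 1:3]
#' @export
computeMoM <- function(cohort, curve = NULL) {
  if (is.null(curve)) {
    curve <- S4Vectors::metadata(cohort)$median_curve
    if (is.null(curve)) curve <- fitMedianCurve(cohort)
  }
  res <- momFromLevels(markerLevels(cohort), curve, gestationalWeeks(cohort))
  SummarizedExperiment::assay(cohort, "mom") <- res$mom
  SummarizedExperiment::assay(cohort, "log10_mom") <- res$log10_mom
  S4Vectors::metadata(cohort)$median_curve <- curve
  S4Vectors::metadata(cohort)$weight_adjusted <- FALSE
  cohort
}

#' Maternal-weight correction model for MoM values
#'
#' Heavier mothers dilute fetoplacental analytes, so expected MoM falls with
#' maternal weight. The conventional correction regresses control MoM on
#' reciprocal weight per marker -- expected MoM = a + b/weight -- and divides
#' each subject's MoM by the expectation at her weight. \code{weightModel}
#' with no arguments returns the identity model (no correction), the default
#' throughout.
#'
#' @param cohort A \linkS4class{ScreeningCohort} with MoM assays; only
#'   controls are used for fitting.
#' @return An object of class \code{"WeightModel"}: a list with
#'   \code{type} ("identity" or "reciprocal") and, for reciprocal models, a
#'   per-marker coefficient matrix.
#' @examples
#' weightModel()   # identity
#' @export
fitWeightModel <- function(cohort) {
  ctrl <- cohort[, subjectGroups(cohort) == "control"]
  if (ncol(ctrl) < 10) stop("need at least 10 controls to fit a weight model")
  mom <- momValues(ctrl)
  w <- maternalWeight(ctrl)
  coefs <- t(vapply(screeningMarkers(), function(mk) {
    stats::coef(stats::lm(mom[mk, ] ~ I(1 / w)))
  }, numeric(2)))
  colnames(coefs) <- c("intercept", "inv_weight")
  structure(list(type = "reciprocal", coefficients = coefs),
            class = "WeightModel")
}

#' @rdname fitWeightModel
#' @export
weightModel <- function() {
  structure(list(type = "identity"), class = "WeightModel")
}

#' Expected MoM at a given maternal weight
#'
#' @param model A \code{"WeightModel"}.
#' @param weight Weights in kg (> 0).
#' @return Markers x length(weight) matrix of expected MoM (all 1 for the
#'   identity model).
#' @export
expectedMoM <- function(model, weight) {
  if (any(weight <= 0)) stop("weight must be > 0")
  if (model$type == "identity") {
    out <- matrix(1, nrow = 4, ncol = length(weight))
  } else {
    cf <- model$coefficients
    out <- vapply(weight, function(w) cf[, "intercept"] + cf[, "inv_weight"] / w,
                  numeric(4))
    out <- matrix(out, nrow = 4)
  }
  rownames(out) <- screeningMarkers()
  out
}

#' Apply maternal-weight correction to MoM assays
#'
#' Divides each subject's MoM by the model's expected MoM at her weight and
#' recomputes log10 MoM; with the identity model the cohort is returned
#' unchanged (apart from the \code{weight_adjusted} flag remaining FALSE).
#'
#' @param cohort A \linkS4class{ScreeningCohort} with MoM assays.
#' @param model A \code{"WeightModel"} from \code{\link{fitWeightModel}} or
#'   \code{\link{weightModel}}.
#' @return The adjusted cohort; \code{metadata()$weight_adjusted} records
#'   whether a non-identity correction was applied.
#' @export
weightAdjust <- function(cohort, model = weightModel()) {
  if (model$type == "identity") {
    S4Vectors::metadata(cohort)$weight_adjusted <- FALSE
    return(cohort)
  }
  mom <- momValues(cohort)
  exp_mom <- expectedMoM(model, maternalWeight(cohort))
  if (any(exp_mom <= 0))
    stop("weight model predicts non-positive expected MoM; refusing to adjust")
  adj <- mom / exp_mom
  SummarizedExperiment::assay(cohort, "mom") <- adj
  SummarizedExperiment::assay(cohort, "log10_mom") <- log10(adj)
  S4Vectors::metadata(cohort)$weight_adjusted <- TRUE
  cohort
}
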