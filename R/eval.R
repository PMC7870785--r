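#' ROCResult: an empirical ROC curve
#'
#' Empirical ROC of a score against a binary label, with trapezoidal AUC,
#' DeLong confidence interval and a DeLong z-test against AUC = 0.5. The
#' empirical AUC equals the Mann-Whitney statistic U / (n1 n0) exactly.
#'
#' @slot points data.frame with \code{cutoff}, \code{fpr}, \code{tpr}
#'   (cutoffs at midpoints of adjacent distinct scores).
#' @slot auc,ciLow,ciHigh,pValue AUC, DeLong 95 percent CI, p vs 0.5.
#' @slot direction "higher_is_positive" or "lower_is_positive".
#' @slot scores,labels The input data (labels as 0/1 integer), retained so
#'   cutoff metrics can count the confusion table.
#' @aliases ROCResult-class
#' @seealso \code{\link{rocCurve}}, \code{\link{youdenCutoff}}
#' @exportClass ROCResult
setClass("ROCResult", representation(
  points = "data.frame", auc = "numeric", ciLow = "numeric",
  ciHigh = "numeric", pValue = "numeric", direction = "character",
  scores = "numeric", labels = "integer"))

#' Empirical ROC curve with DeLong inference
#'
#' @param scores Numeric scores (e.g. MoM values or posterior risks).
#' @param labels Binary labels: 1/TRUE = affected (case), 0/FALSE = control.
#' @param direction "auto" (default) infers polarity from the sign of the
#'   case-vs-control mean difference; "higher_is_positive" /
#'   "lower_is_positive" force it. With lower_is_positive, small scores call
#'   a subject positive (e.g. sHLA-G MoM in trisomy 18).
#' @param conf Confidence level for the DeLong CI (default 0.95).
#' @return A \linkS4class{ROCResult}.
#' @examples
#' r <- rocCurve(c(1, 2, 3, 4), c(0, 1, 0, 1))
#' aucValue(r)   # 0.75
#' @importFrom pROC roc coords ci.auc var
#' @export
rocCurve <- function(scores, labels, direction = c("auto",
                     "higher_is_positive", "lower_is_positive"),
                     conf = 0.95) {
  direction <- match.arg(direction)
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(labels)) < 2)
    stop("both classes (cases and controls) must be present")
  if (direction == "auto") {
    direction <- if (mean(scores[labels == 1]) >= mean(scores[labels == 0]))
      "higher_is_positive" else "lower_is_positive"
  }
  dir <- if (direction == "higher_is_positive") "<" else ">"
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = dir, quiet = TRUE)
  co <- pROC::coords(r, "all", ret = c("threshold", "specificity",
                                       "sensitivity"), transpose = FALSE)
  pts <- data.frame(cutoff = co$threshold, fpr = 1 - co$specificity,
                    tpr = co$sensitivity)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  auc <- as.numeric(pROC::auc(r))
  # pROC warns on degenerate (AUC = 1) curves; the zero-variance case is
  # handled explicitly below
  ci <- suppressWarnings(as.numeric(
    pROC::ci.auc(r, conf.level = conf, method = "delong")))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  p <- if (v > 0) 2 * stats::pnorm(-abs((auc - 0.5) / sqrt(v))) else
    if (auc == 0.5) 1 else 0  # degenerate variance (perfect separation)
  methods::new("ROCResult", points = pts, auc = auc,
               ciLow = min(ci[1], ci[3]), ciHigh = max(ci[1], ci[3]),
               pValue = p, direction = direction,
               scores = as.numeric(scores), labels = labels)
}

#' @describeIn rocCurve the area under the curve.
#' @param x A \linkS4class{ROCResult}.
#' @export
aucValue <- function(x) x@auc

#' @describeIn rocCurve the ROC points (cutoff, fpr, tpr).
#' @export
rocPoints <- function(x) x@points

#' @describeIn rocCurve compact display.
#' @param object A \linkS4class{ROCResult}.
#' @export
setMethod("show", "ROCResult", function(object) {
  cat(sprintf(
    "ROC (%s): AUC = %.3f (95%% CI %.3f-%.3f), p = %.3g, %d points\n",
    object@direction, object@auc, object@ciLow, object@ciHigh,
    object@pValue, nrow(object@points)))
  invisible(NULL)
})

#' CutoffMetrics: a screening test at one operating point
#'
#' Confusion counts and the derived metrics at a single cutoff: sensitivity
#' tp/(tp+fn), specificity tn/(tn+fp), predictive values ppv = tp/(tp+fp)
#' and npv = tn/(tn+fn), and likelihood ratios plr = sens/(1-spec), nlr =
#' (1-sens)/spec.
#'
#' @slot cutoff Score cutoff (NA when built from rates alone).
#' @slot sensitivity,specificity,ppv,npv Rates in [0, 1].
#' @slot plr,nlr Positive/negative likelihood ratios.
#' @slot counts Named integer (tp, fp, fn, tn).
#' @slot youden Youden index J = sensitivity + specificity - 1.
#' @aliases CutoffMetrics-class
#' @exportClass CutoffMetrics
setClass("CutoffMetrics", representation(
  cutoff = "numeric", sensitivity = "numeric", specificity = "numeric",
  ppv = "numeric", npv = "numeric", plr = "numeric", nlr = "numeric",
  counts = "integer", youden = "numeric"))

.metricsFromCounts <- function(tp, fp, fn, tn, cutoff = NA_real_) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  methods::new("CutoffMetrics", cutoff = cutoff,
               sensitivity = sens, specificity = spec,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
               plr = if (spec < 1) sens / (1 - spec) else Inf,
               nlr = if (spec > 0) (1 - sens) / spec else Inf,
               counts = c(tp = as.integer(tp), fp = as.integer(fp),
                          fn = as.integer(fn), tn = as.integer(tn)),
               youden = sens + spec - 1)
}

#' @describeIn metricsFromRates compact display.
#' @param object A \linkS4class{CutoffMetrics}.
#' @export
setMethod("show", "CutoffMetrics", function(object) {
  cat(sprintf(paste0(
    "Cutoff %s: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%, ",
    "PLR %.2f, NLR %.2f (tp %d, fp %d, fn %d, tn %d)\n"),
    ifelse(is.na(object@cutoff), "(from rates)",
           format(object@cutoff, digits = 4)),
    100 * object@sensitivity, 100 * object@specificity, 100 * object@ppv,
    100 * object@npv, object@plr, object@nlr,
    object@counts["tp"], object@counts["fp"], object@counts["fn"],
    object@counts["tn"]))
  invisible(NULL)
})

#' Predictive values and likelihood ratios from published rates
#'
#' Reconstructs the confusion table implied by a reported sensitivity and
#' specificity at known group sizes (tp = round(sens x n_case), tn =
#' round(spec x n_ctrl)) and derives PPV, NPV, PLR and NLR from the integer
#' counts -- the arithmetic linking a screening table's rate rows to its
#' predictive-value rows.
#'
#' @param sensitivity,specificity Rates in [0, 1].
#' @param nCase,nCtrl Positive group sizes.
#' @return A \linkS4class{CutoffMetrics}.
#' @examples
#' m <- metricsFromRates(0.855, 0.887, 83, 797)
#' c(ppv = ppvValue(m), npv = npvValue(m))   # 0.441, 0.983
#' @export
metricsFromRates <- function(sensitivity, specificity, nCase, nCtrl) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    stop("rates must lie in [0, 1]")
  if (nCase <= 0 || nCtrl <= 0) stop("group sizes must be positive")
  tp <- round(sensitivity * nCase)
  tn <- round(specificity * nCtrl)
  .metricsFromCounts(tp = tp, fp = nCtrl - tn, fn = nCase - tp, tn = tn)
}

#' @describeIn metricsFromRates sensitivity.
#' @param x A \linkS4class{CutoffMetrics}.
#' @export
sensitivityValue <- function(x) x@sensitivity

#' @describeIn metricsFromRates specificity.
#' @export
specificityValue <- function(x) x@specificity

#' @describeIn metricsFromRates positive predictive value.
#' @export
ppvValue <- function(x) x@ppv

#' @describeIn metricsFromRates negative predictive value.
#' @export
npvValue <- function(x) x@npv

#' @describeIn metricsFromRates positive likelihood ratio.
#' @export
plrValue <- function(x) x@plr

#' @describeIn metricsFromRates negative likelihood ratio.
#' @export
nlrValue <- function(x) x@nlr

#' @describeIn metricsFromRates confusion counts (tp, fp, fn, tn).
#' @export
confusionCounts <- function(x) x@counts

#' Youden-index optimal cutoff
#'
#' Selects the ROC operating point maximizing Youden's J = sensitivity +
#' specificity - 1 (ties broken toward higher sensitivity) and returns the
#' full confusion table at that cutoff. Cutoffs lie at midpoints of adjacent
#' distinct scores; positivity is score > cutoff (higher_is_positive) or
#' score < cutoff (lower_is_positive).
#'
#' @param roc A \linkS4class{ROCResult}.
#' @return A \linkS4class{CutoffMetrics}.
#' @examples
#' r <- rocCurve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' youdenCutoff(r)   # J = 1 at the midpoint 6.5
#' @export
youdenCutoff <- function(roc) {
  pts <- roc@points
  fin <- is.finite(pts$cutoff)
  if (!any(fin)) stop("degenerate ROC: no finite cutoffs")
  pts <- pts[fin, , drop = FALSE]
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(pts$tpr[best])]
  cut <- pts$cutoff[best]
  pos <- if (roc@direction == "higher_is_positive")
    roc@scores > cut else roc@scores < cut
  tp <- sum(pos & roc@labels == 1L); fn <- sum(!pos & roc@labels == 1L)
  fp <- sum(pos & roc@labels == 0L); tn <- sum(!pos & roc@labels == 0L)
  .metricsFromCounts(tp, fp, fn, tn, cutoff = cut)
}

#' Detection rate at a fixed false-positive rate
#'
#' Places the cutoff at the control quantile such that at most
#' \code{targetFpr} of controls screen positive (empirical step-function
#' convention) and reports the fraction of cases beyond it -- the detection
#' rate (sensitivity) at that false-positive rate, the standard operating
#' summary of a screening protocol.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = case).
#' @param targetFpr Target false-positive rate in (0, 1), e.g. 0.05.
#' @param direction As in \code{\link{rocCurve}}.
#' @return List: \code{detection_rate}, \code{cutoff} (on the original score
#'   scale), \code{achieved_fpr} (always <= targetFpr), \code{n_case},
#'   \code{n_ctrl}.
#' @examples
#' s <- c(rnorm(100), rnorm(100, 2)); l <- rep(0:1, each = 100)
#' detectionRateAtFPR(s, l, 0.05)$detection_rate
#' @export
detectionRateAtFPR <- function(scores, labels,
                               targetFpr = 0.05,
                               direction = c("auto", "higher_is_positive",
                                             "lower_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (direction == "auto") {
    direction <- if (mean(scores[labels == 1]) >= mean(scores[labels == 0]))
      "higher_is_positive" else "lower_is_positive"
  }
  s <- if (direction == "higher_is_positive") scores else -scores
  ctrl <- s[labels == 0L]; case <- s[labels == 1L]
  cut <- fprCutoff(ctrl, targetFpr)
  list(detection_rate = mean(case >= cut),
       cutoff = if (direction == "higher_is_positive") cut else -cut,
       achieved_fpr = mean(ctrl >= cut),
       n_case = length(case), n_ctrl = length(ctrl))
}

#' LogisticFit: a multivariate logistic regression
#'
#' @slot table data.frame per term: \code{term}, \code{coefficient},
#'   \code{exp_b}, \code{ci_low}, \code{ci_high} (Wald 95 percent CI on
#'   Exp(B)), \code{p_value}.
#' @slot converged Logical; FALSE when IRLS failed or separation was
#'   detected.
#' @slot separation Logical separation flag.
#' @slot nIterations IRLS iteration count.
#' @slot n Number of observations.
#' @aliases LogisticFit-class
#' @exportClass LogisticFit
setClass("LogisticFit", representation(
  table = "data.frame", converged = "logical", separation = "logical",
  nIterations = "integer", n = "integer"))

#' Multivariate logistic regression with Wald odds-ratio CIs
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via \code{\link[stats]{glm}}) of a binary outcome on a covariate
#' matrix, reporting Exp(B) with Wald 95 percent confidence intervals and
#' p-values per covariate -- the standard risk-factor table for a screened
#' cohort (age, weight and the four marker MoMs against trisomy status).
#' Perfect or quasi-perfect separation (fitted probabilities numerically 0
#' or 1) is flagged and the fit reported unconverged.
#'
#' @param covariates Numeric matrix or data.frame (n x p), no constant
#'   columns (the intercept is added internally).
#' @param outcome Binary outcome (1 = case).
#' @param conf Confidence level (default 0.95).
#' @return A \linkS4class{LogisticFit}.
#' @examples
#' x <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
#' y <- rbinom(100, 1, plogis(x[, 1]))
#' logisticFit(x, y)
#' @export
logisticFit <- function(covariates, outcome, conf = 0.95) {
  x <- as.data.frame(covariates)
  y <- as.integer(as.logical(outcome))
  if (nrow(x) != length(y)) stop("covariates/outcome length mismatch")
  if (nrow(x) <= ncol(x) + 1) stop("need more observations than covariates")
  const <- vapply(x, function(v) stats::var(as.numeric(v)) == 0, logical(1))
  if (any(const))
    stop("constant covariate column(s): ",
         paste(names(x)[const], collapse = ", "))
  dat <- cbind(x, .outcome = y)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.outcome ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tab <- data.frame(
    term = rownames(sm),
    coefficient = sm[, "Estimate"],
    exp_b = exp(sm[, "Estimate"]),
    ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    p_value = sm[, "Pr(>|z|)"],
    row.names = NULL)
  methods::new("LogisticFit", table = tab,
               converged = fit$converged && !separation,
               separation = separation,
               nIterations = as.integer(fit$iter), n = length(y))
}

#' @describeIn logisticFit the coefficient table.
#' @param x A \linkS4class{LogisticFit}.
#' @export
coefficientTable <- function(x) x@table

#' @describeIn logisticFit compact display.
#' @param object A \linkS4class{LogisticFit}.
#' @export
setMethod("show", "LogisticFit", function(object) {
  cat("Logistic regression (n =", object@n, ")",
      if (!object@converged) "[NOT CONVERGED]",
      if (object@separation) "[SEPARATION]", "\n")
  tab <- object@table
  tab$exp_b <- signif(tab$exp_b, 4)
  tab$ci_low <- signif(tab$ci_low, 4)
  tab$ci_high <- signif(tab$ci_high, 4)
  tab$p_value <- signif(tab$p_value, 3)
  tab$coefficient <- signif(tab$coefficient, 4)
  print(tab, row.names = FALSE)
  invisible(NULL)
})
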