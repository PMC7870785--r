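#' PriorModel: prior (pre-marker) trisomy risk
#'
#' The marker likelihood ratio multiplies a prior risk expressed as odds. The
#' prior is either flat per trisomy (default: birth prevalences of 1/5000
#' for trisomy 18 and, by screening convention, 1/700 for trisomy 21) or
#' looked up from a maternal-age table supplied by the user.
#'
#' @slot mode "flat" or "age_table".
#' @slot flat Named numeric of flat prior probabilities per trisomy.
#' @slot ageTable data.frame with columns \code{age}, \code{T21}, \code{T18}
#'   (prior probability at each completed year of age); empty for flat mode.
#' @aliases PriorModel-class
#' @exportClass PriorModel
setClass("PriorModel", representation(
  mode = "character", flat = "numeric", ageTable = "data.frame"))

setValidity("PriorModel", function(object) {
  if (!object@mode %in% c("flat", "age_table")) return("unknown prior mode")
  pr <- object@flat
  if (object@mode == "flat" &&
      (any(pr <= 0) || any(pr >= 1))) return("flat priors must be in (0, 1)")
  if (object@mode == "age_table") {
    at <- object@ageTable
    if (!all(c("age", "T21", "T18") %in% colnames(at)))
      return("ageTable needs columns age, T21, T18")
    if (any(at$T21 <= 0 | at$T21 >= 1 | at$T18 <= 0 | at$T18 >= 1))
      return("age-table priors must be in (0, 1)")
  }
  TRUE
})

#' Construct a PriorModel
#'
#' @param T21,T18 Flat prior probabilities (defaults 1/700 and 1/5000).
#' @param ageTable Optional data.frame (\code{age}, \code{T21}, \code{T18});
#'   when given, priors are looked up by completed year of maternal age
#'   (nearest tabulated age).
#' @return A \linkS4class{PriorModel}.
#' @examples
#' priorModel()                      # flat defaults
#' priorModel(T18 = 1/2500)
#' @export
priorModel <- function(T21 = 1 / 700, T18 = 1 / 5000, ageTable = NULL) {
  if (is.null(ageTable)) {
    methods::new("PriorModel", mode = "flat",
                 flat = c(T21 = T21, T18 = T18), ageTable = data.frame())
  } else {
    methods::new("PriorModel", mode = "age_table",
                 flat = c(T21 = T21, T18 = T18), ageTable = ageTable)
  }
}

#' Prior probability for subjects
#'
#' @param model A \linkS4class{PriorModel}.
#' @param trisomy "T21" or "T18".
#' @param age Maternal ages (used only in age_table mode).
#' @return Numeric vector of prior probabilities.
#' @export
priorProbability <- function(model, trisomy, age = NULL) {
  trisomy <- match.arg(trisomy, c("T21", "T18"))
  if (model@mode == "flat") {
    p <- unname(model@flat[trisomy])
    return(if (is.null(age)) p else rep(p, length(age)))
  }
  if (is.null(age)) stop("age required for an age-table prior")
  idx <- vapply(age, function(a) which.min(abs(model@ageTable$age - a)),
                integer(1))
  model@ageTable[[trisomy]][idx]
}

# log density of a multivariate normal via Cholesky; x is a matrix (rows =
# observations). Kept internal: the risk engine's density ratio is the one
# place a joint Gaussian is evaluated.
.dmvnormLog <- function(x, mean, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  d <- length(mean)
  z <- backsolve(ch, t(x) - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Gaussian likelihood ratio of a marker profile
#'
#' The core screening statistic: the ratio of the probability density of a
#' log10 MoM profile under the affected group's Gaussian to its density under
#' the unaffected group's Gaussian. With \code{useCorrelations = FALSE}
#' (default) the markers are treated as independent and the LR is the product
#' of four univariate normal density ratios; with TRUE the full multivariate
#' normal densities with covariance D R D per group are used. Markers whose
#' group means are closer together relative to their SDs contribute less --
#' the smaller the SDs and the larger the mean separation, the more
#' discriminating the analyte.
#'
#' @param logMoM Numeric 4-vector (marker order) or n x 4 matrix of log10
#'   MoM profiles.
#' @param affected,unaffected \linkS4class{GroupParams} of the affected
#'   (trisomy) and unaffected (control) groups.
#' @param useCorrelations Use the full covariance (default FALSE: the printed
#'   correlations are rounded and partly non-significant).
#' @param markers Subset of markers to use (default all four).
#' @return Positive likelihood ratio(s), one per profile.
#' @examples
#' p <- table2Params()
#' # profile at the control means: strong evidence against T18
#' likelihoodRatio(groupMean(p$control), p$T18, p$control)
#' @export
likelihoodRatio <- function(logMoM, affected, unaffected,
                            useCorrelations = FALSE,
                            markers = screeningMarkers()) {
  x <- if (is.matrix(logMoM)) logMoM else matrix(logMoM, nrow = 1)
  idx <- match(markers, screeningMarkers())
  if (anyNA(idx)) stop("unknown marker(s): ",
                       paste(markers[is.na(idx)], collapse = ", "))
  if (ncol(x) == length(screeningMarkers())) {
    xm <- x[, idx, drop = FALSE]
  } else if (ncol(x) == length(idx)) {
    xm <- x
  } else {
    stop("logMoM must have 4 columns, or one per requested marker")
  }
  m1 <- affected@mean[idx]; s1 <- affected@sd[idx]
  m0 <- unaffected@mean[idx]; s0 <- unaffected@sd[idx]
  if (any(c(s1, s0) <= 0)) stop("group SDs must be positive for a density ratio")
  if (!useCorrelations) {
    ll <- vapply(seq_along(idx), function(j)
      stats::dnorm(xm[, j], m1[j], s1[j], log = TRUE) -
        stats::dnorm(xm[, j], m0[j], s0[j], log = TRUE),
      numeric(nrow(xm)))
    loglr <- if (nrow(xm) == 1L) sum(ll) else rowSums(ll)
  } else {
    S1 <- groupCovariance(affected)[idx, idx, drop = FALSE]
    S0 <- groupCovariance(unaffected)[idx, idx, drop = FALSE]
    loglr <- .dmvnormLog(xm, m1, S1) - .dmvnormLog(xm, m0, S0)
  }
  unname(exp(loglr))
}

#' Posterior risk from prior and likelihood ratio
#'
#' Odds-form Bayes update: posterior odds = prior odds x LR, reported as a
#' probability. Strictly increasing in both arguments; equal to the prior at
#' LR = 1.
#'
#' @param prior Prior probability/probabilities in (0, 1).
#' @param lr Positive likelihood ratio(s).
#' @return Posterior probability/probabilities.
#' @examples
#' posteriorRisk(1 / 5000, 171)   # ~0.0331
#' @export
posteriorRisk <- function(prior, lr) {
  if (any(prior <= 0 | prior >= 1)) stop("prior must be in (0, 1)")
  if (any(lr <= 0)) stop("likelihood ratio must be positive")
  odds <- prior / (1 - prior) * lr
  odds / (1 + odds)
}

#' Score a cohort for trisomy risk
#'
#' Runs the full risk calculation for every subject and each requested
#' trisomy: log10 MoM profile -> Gaussian likelihood ratio (affected vs
#' control parameters) -> posterior risk via the prior model. Screen-positive
#' calls use either a fixed posterior-risk threshold or, when
#' \code{targetFpr} is given, a threshold placed at the control posterior
#' quantile so that at most that fraction of controls screens positive
#' (mirroring a fixed 5 percent false-positive rate protocol).
#'
#' @param cohort A \linkS4class{ScreeningCohort} with MoM assays.
#' @param paramsByGroup Named list of \linkS4class{GroupParams} including
#'   "control" and each scored trisomy; default: estimated from the cohort by
#'   \code{\link{summarizeGroup}}.
#' @param prior A \linkS4class{PriorModel} (default \code{priorModel()}).
#' @param trisomies Which trisomies to score (default c("T21", "T18")).
#' @param threshold Fixed posterior-risk cutoff for screen positivity
#'   (ignored when \code{targetFpr} is given).
#' @param targetFpr Optional control false-positive rate in (0, 1) at which
#'   to place the cutoff (requires control subjects in the cohort).
#' @param useCorrelations Passed to \code{\link{likelihoodRatio}}.
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{trisomy}, \code{prior}, \code{lr}, \code{posterior},
#'   \code{screen_positive}, \code{used_correlations}.
#' @examples
#' coh <- computeMoM(generateCohort(simulationConfig(
#'   groupSizes = c(control = 100, T21 = 0, T18 = 20), seed = 4)))
#' head(scoreCohort(coh, paramsByGroup = table2Params(),
#'                  trisomies = "T18", targetFpr = 0.05))
#' @export
scoreCohort <- function(cohort, paramsByGroup = NULL, prior = priorModel(),
                        trisomies = c("T21", "T18"), threshold = 1 / 250,
                        targetFpr = NULL, useCorrelations = FALSE) {
  if (is.null(paramsByGroup)) {
    present <- unique(as.character(subjectGroups(cohort)))
    paramsByGroup <- lapply(intersect(screeningGroups(), present),
                            function(g) summarizeGroup(cohort, g))
    names(paramsByGroup) <- intersect(screeningGroups(), present)
  }
  if (is.null(paramsByGroup$control))
    stop("paramsByGroup must include 'control'")
  lm <- t(log10MoM(cohort))
  grp <- as.character(subjectGroups(cohort))
  out <- lapply(trisomies, function(tr) {
    if (is.null(paramsByGroup[[tr]]))
      stop("no GroupParams for trisomy '", tr, "'")
    lr <- likelihoodRatio(lm, paramsByGroup[[tr]], paramsByGroup$control,
                          useCorrelations = useCorrelations)
    pr <- priorProbability(prior, tr, maternalAge(cohort))
    post <- posteriorRisk(pr, lr)
    cut <- threshold
    if (!is.null(targetFpr)) {
      if (targetFpr <= 0 || targetFpr >= 1) stop("targetFpr must be in (0, 1)")
      ctrl_post <- post[grp == "control"]
      if (!length(ctrl_post)) stop("targetFpr mode requires control subjects")
      cut <- fprCutoff(ctrl_post, targetFpr)
    }
    data.frame(subject_id = colnames(cohort), group = grp, trisomy = tr,
               prior = pr, lr = lr, posterior = post,
               screen_positive = post >= cut,
               used_correlations = useCorrelations, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Cutoff achieving at most a target false-positive rate
#'
#' Smallest observed-score cutoff such that the fraction of control scores at
#' or above it does not exceed \code{targetFpr} (step-function convention;
#' scores are "higher is positive").
#'
#' @param controlScores Numeric control scores.
#' @param targetFpr Target false-positive rate in (0, 1).
#' @return Scalar cutoff (a value from \code{controlScores} scaled slightly
#'   up is not used; positivity is \code{score >= cutoff}).
#' @export
fprCutoff <- function(controlScores, targetFpr) {
  if (targetFpr <= 0 || targetFpr >= 1) stop("targetFpr must be in (0, 1)")
  n <- length(controlScores)
  if (n < 1 / targetFpr)
    stop("too few controls (", n, ") to resolve a false-positive rate of ",
         targetFpr)
  k <- floor(n * targetFpr)   # at most k controls may be >= cutoff
  x <- sort(controlScores)
  u <- unique(x)
  cntGe <- n - match(u, x) + 1L          # controls at or above each value
  ok <- which(cntGe <= k)
  if (length(ok)) return(u[min(ok)])     # smallest admissible cutoff
  u[length(u)] + max(abs(u[length(u)]) * 1e-12, .Machine$double.xmin)
}
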