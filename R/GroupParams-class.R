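#' GroupParams: the Gaussian parameters of one screening group
#'
#' The binormal screening model treats each marker's log10 MoM as Gaussian
#' within a group; a group is then fully described by a mean vector, an SD
#' vector and a 4x4 correlation matrix on the log10 MoM scale, plus the
#' group's median MoM per marker and its size. These parameters drive both the
#' cohort simulator and the likelihood-ratio risk engine.
#'
#' @slot group Group label ("control", "T21" or "T18").
#' @slot mean Named numeric, mean log10 MoM per marker.
#' @slot sd Named numeric, SD of log10 MoM per marker (positive; may be 0 only
#'   in degenerate summaries).
#' @slot correlation 4x4 correlation matrix (symmetric, unit diagonal,
#'   entries in [-1, 1]; NA allowed where undefined).
#' @slot medianMoM Named numeric, median MoM per marker.
#' @slot n Integer group size.
#' @aliases GroupParams-class
#' @seealso \code{\link{groupParams}}, \code{\link{table2Params}},
#'   \code{\link{summarizeGroup}}, \code{\link{likelihoodRatio}}
#' @exportClass GroupParams
setClass("GroupParams", representation(
  group = "character", mean = "numeric", sd = "numeric",
  correlation = "matrix", medianMoM = "numeric", n = "integer"))

setValidity("GroupParams", function(object) {
  mk <- screeningMarkers()
  if (!identical(names(object@mean), mk)) return("mean must be named by marker")
  if (!identical(names(object@sd), mk)) return("sd must be named by marker")
  if (any(object@sd < 0, na.rm = TRUE)) return("sd must be non-negative")
  R <- object@correlation
  if (!all(dim(R) == c(4L, 4L))) return("correlation must be 4x4")
  off <- R[upper.tri(R)]
  if (any(abs(off[!is.na(off)]) > 1)) return("correlations must lie in [-1, 1]")
  if (any(abs(diag(R) - 1) > 1e-12, na.rm = TRUE))
    return("correlation diagonal must be 1")
  if (any(abs(R - t(R)) > 1e-12, na.rm = TRUE))
    return("correlation matrix must be symmetric")
  TRUE
})

#' Construct a GroupParams
#'
#' @param group Group label.
#' @param mean,sd Numeric 4-vectors (marker order of
#'   \code{\link{screeningMarkers}}) of mean and SD log10 MoM.
#' @param correlation 4x4 correlation matrix of log10 MoM.
#' @param medianMoM Numeric 4-vector of median MoM (defaults to NA).
#' @param n Group size (defaults to NA).
#' @return A \linkS4class{GroupParams}.
#' @examples
#' table2Params()$T18
#' @export
groupParams <- function(group, mean, sd, correlation = diag(4),
                        medianMoM = rep(NA_real_, 4), n = NA_integer_) {
  mk <- screeningMarkers()
  mean <- stats::setNames(as.numeric(mean), mk)
  sd <- stats::setNames(as.numeric(sd), mk)
  medianMoM <- stats::setNames(as.numeric(medianMoM), mk)
  correlation <- as.matrix(correlation)
  dimnames(correlation) <- list(mk, mk)
  methods::new("GroupParams", group = as.character(group), mean = mean,
               sd = sd, correlation = correlation, medianMoM = medianMoM,
               n = as.integer(n))
}

#' @describeIn groupParams mean log10 MoM vector.
#' @param x,object A \linkS4class{GroupParams}.
#' @export
groupMean <- function(x) x@mean

#' @describeIn groupParams SD log10 MoM vector.
#' @export
groupSD <- function(x) x@sd

#' @describeIn groupParams correlation matrix of log10 MoM.
#' @export
groupCorrelation <- function(x) x@correlation

#' @describeIn groupParams median MoM vector.
#' @export
groupMedianMoM <- function(x) x@medianMoM

#' @describeIn groupParams group size.
#' @export
groupSize <- function(x) x@n

#' Covariance matrix implied by a GroupParams
#'
#' Builds the log10 MoM covariance Sigma = D R D from the SD vector (D, as a
#' diagonal matrix) and the correlation matrix R, optionally repairing a
#' non-positive-definite result (printed correlations are rounded, so D R D
#' can fall marginally outside the PD cone) by clipping eigenvalues at 1e-10.
#'
#' @param params A \linkS4class{GroupParams}.
#' @param repair Apply the nearest-PD eigenvalue clip if needed (default TRUE;
#'   a warning reports the repair).
#' @return 4x4 covariance matrix.
#' @export
groupCovariance <- function(params, repair = TRUE) {
  D <- diag(params@sd)
  S <- D %*% params@correlation %*% D
  dimnames(S) <- dimnames(params@correlation)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    if (!repair)
      stop("covariance for group '", params@group, "' is not positive definite")
    warning("covariance for group '", params@group,
            "' not positive definite; clipping eigenvalues at 1e-10")
    S <- ev$vectors %*% diag(pmax(ev$values, 1e-10)) %*% t(ev$vectors)
    dimnames(S) <- dimnames(params@correlation)
    if (min(eigen(S, symmetric = TRUE)$values) <= 0)
      stop("covariance for group '", params@group,
           "' remains non-positive-definite after repair")
  }
  S
}

#' @describeIn groupParams compact display.
#' @export
setMethod("show", "GroupParams", function(object) {
  cat("GroupParams for group '", object@group, "' (n = ", object@n, ")\n",
      sep = "")
  tab <- rbind(`median MoM` = object@medianMoM,
               `mean log10 MoM` = object@mean,
               `sd log10 MoM` = object@sd)
  print(round(tab, 4))
  cat("correlation (log10 MoM):\n")
  print(round(object@correlation, 3))
  invisible(NULL)
})

#' Published distribution parameters of the study population
#'
#' Loads the per-group log10 MoM means, SDs, pairwise Pearson correlations,
#' median MoMs and group sizes (797 controls, 139 T21, 83 T18) that
#' characterize the reference second-trimester cohort, together with the
#' control median sHLA-G level of 106.3 U/ml. These parameters are shipped as
#' \code{inst/extdata/params_table2.json} and are the defaults for
#' \code{\link{simulationConfig}} and \code{\link{likelihoodRatio}}.
#'
#' @param path JSON file to read; defaults to the bundled parameter file.
#' @return Named list of \linkS4class{GroupParams} (control, T21, T18), with
#'   attributes \code{group_sizes}, \code{control_medians} (list usable by
#'   \code{\link{medianCurve}}) and \code{demographics}.
#' @examples
#' p <- table2Params()
#' groupMean(p$T18)["shla_g"]   # -0.3269
#' @export
table2Params <- function(path = system.file("extdata", "params_table2.json",
                                            package = "momscreen")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- screeningMarkers()
  out <- lapply(names(raw$groups), function(g) {
    gp <- raw$groups[[g]]
    R <- as.matrix(gp$correlation)
    groupParams(g, mean = gp$mean_log10_mom, sd = gp$sd_log10_mom,
                correlation = R, medianMoM = gp$median_mom,
                n = raw$group_sizes[[g]])
  })
  names(out) <- names(raw$groups)
  attr(out, "group_sizes") <- unlist(raw$group_sizes)
  cm <- lapply(raw$control_medians, function(v)
    if (length(v) == 1L) as.numeric(v) else unlist(v))
  attr(out, "control_medians") <- cm
  attr(out, "demographics") <- raw$demographics
  out
}
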