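#' SimulationConfig: everything a cohort simulation needs
#'
#' Fully specifies a synthetic screening cohort: group sizes, the per-group
#' Gaussian log10 MoM parameters (\linkS4class{GroupParams}), the control
#' median curve used to turn MoMs back into raw concentrations, demographic
#' ranges and the seed. The bundled defaults reproduce the reference study
#' population: 797 controls, 139 T21 and 83 T18 pregnancies with the
#' published log10 MoM means, SDs and correlations, maternal age 18--35
#' years, median weight 54.5 kg and gestational weeks 15--19.
#'
#' @slot groupSizes Named integer vector (control, T21, T18), all >= 0.
#' @slot groupParams Named list of \linkS4class{GroupParams}.
#' @slot medianCurve \linkS4class{MedianCurve} of control medians.
#' @slot ageRange Numeric length-2, within [18, 35].
#' @slot weightMedian Median maternal weight (kg).
#' @slot weightSdLog SD of log weight (lognormal weight model).
#' @slot weekRange Integer length-2 within [15, 19].
#' @slot seed Integer RNG seed; all randomness in \code{\link{generateCohort}}
#'   derives from it.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  groupSizes = "integer", groupParams = "list", medianCurve = "MedianCurve",
  ageRange = "numeric", weightMedian = "numeric", weightSdLog = "numeric",
  weekRange = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (any(object@groupSizes < 0)) return("group sizes must be >= 0")
  if (!all(names(object@groupSizes) %in% screeningGroups()))
    return("group size names must be control/T21/T18")
  for (g in names(object@groupSizes))
    if (object@groupSizes[[g]] > 0 && is.null(object@groupParams[[g]]))
      return(paste("missing GroupParams for group", g))
  gp <- object@groupParams
  if (any(vapply(gp, function(p) any(p@sd <= 0), logical(1))))
    return("all group SDs must be > 0 for simulation")
  ar <- object@ageRange
  if (length(ar) != 2 || ar[1] >= ar[2] || ar[1] < 18 || ar[2] > 35)
    return("ageRange must be increasing and within [18, 35]")
  wr <- object@weekRange
  if (length(wr) != 2 || wr[1] > wr[2] || wr[1] < 15L || wr[2] > 19L)
    return("weekRange must be within [15, 19]")
  if (object@weightMedian <= 0 || object@weightSdLog <= 0)
    return("weight model parameters must be positive")
  TRUE
})

#' Construct a SimulationConfig
#'
#' @param groupSizes Named vector of subjects per group; default the study
#'   sizes \code{c(control = 797, T21 = 139, T18 = 83)}.
#' @param groupParams Named list of \linkS4class{GroupParams}; default
#'   \code{\link{table2Params}()}.
#' @param medianCurve \linkS4class{MedianCurve}; default
#'   \code{\link{defaultMedianCurve}()}.
#' @param ageRange,weekRange Demographic ranges (defaults 18--35 years,
#'   weeks 15--19).
#' @param weightMedian,weightSdLog Lognormal maternal-weight model (defaults
#'   54.5 kg and 0.14, giving a realistic ~[37, 93] kg range at n ~ 800).
#' @param seed Integer seed (default 1).
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 42)
#' @export
simulationConfig <- function(groupSizes = NULL, groupParams = NULL,
                             medianCurve = NULL, ageRange = c(18, 35),
                             weightMedian = 54.5, weightSdLog = 0.14,
                             weekRange = c(15L, 19L), seed = 1L) {
  defaults <- table2Params()
  if (is.null(groupParams)) groupParams <- defaults[screeningGroups()]
  if (is.null(groupSizes)) groupSizes <- attr(defaults, "group_sizes")
  if (is.null(medianCurve)) medianCurve <- defaultMedianCurve()
  gs <- stats::setNames(as.integer(groupSizes), names(groupSizes))
  methods::new("SimulationConfig", groupSizes = gs,
               groupParams = groupParams, medianCurve = medianCurve,
               ageRange = as.numeric(ageRange),
               weightMedian = weightMedian, weightSdLog = weightSdLog,
               weekRange = as.integer(weekRange), seed = as.integer(seed))
}

#' Default control median curve
#'
#' The bundled median curve: log-linear medians per gestational week for AFP,
#' free beta-hCG and uE3 (arbitrary but fixed concentration units -- they
#' cancel in MoM) and a flat 106.3 U/ml median for sHLA-G, which does not
#' vary with gestational age.
#'
#' @return A \linkS4class{MedianCurve}.
#' @export
defaultMedianCurve <- function() {
  medianCurve(attr(table2Params(), "control_medians"))
}

#' Draw log10 MoM vectors for one group
#'
#' Samples from the multivariate normal distribution on the log10 MoM scale
#' implied by a group's mean vector, SD vector and correlation matrix
#' (covariance D R D, nearest-PD-repaired if the printed correlations are
#' marginally inconsistent). This is the generative counterpart of the
#' binormal risk model: marker levels are lognormal within a group, so log10
#' MoM is Gaussian.
#'
#' @param params A \linkS4class{GroupParams}.
#' @param n Number of draws.
#' @param seed Optional integer seed; when NULL the current RNG state is used
#'   (so callers such as \code{\link{generateCohort}} can thread one seed
#'   through all sampling).
#' @return n x 4 matrix of log10 MoM, columns in marker order.
#' @examples
#' x <- sampleLogMoM(table2Params()$control, 5, seed = 1)
#' @importFrom MASS mvrnorm
#' @export
sampleLogMoM <- function(params, n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  S <- groupCovariance(params)
  x <- MASS::mvrnorm(n, mu = params@mean, Sigma = S)
  if (n == 1L) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(params@mean)))
  colnames(x) <- screeningMarkers()
  x
}

#' Rebuild raw marker levels from log10 MoM
#'
#' Inverts the MoM definition: level = 10^(log10 MoM) x median(marker, week).
#' Exact round trip with \code{\link{momFromLevels}} by construction.
#'
#' @param logMoM Numeric 4-vector (or n x 4 matrix) of log10 MoM in marker
#'   order.
#' @param curve A \linkS4class{MedianCurve}.
#' @param week Integer gestational week (scalar, or one per row).
#' @return Levels in the same shape as \code{logMoM}.
#' @examples
#' reconstructLevels(c(0, 0, 0, 0), defaultMedianCurve(), 16)
#' @export
reconstructLevels <- function(logMoM, curve, week) {
  if (is.matrix(logMoM)) {
    week <- rep_len(week, nrow(logMoM))
    uw <- unique(week)
    medByWeek <- vapply(uw, function(w) .mediansAt(curve, w), numeric(4))
    out <- 10^logMoM * t(medByWeek[, match(week, uw), drop = FALSE])
    colnames(out) <- screeningMarkers()
    return(out)
  }
  med <- .mediansAt(curve, week)
  stats::setNames(10^as.numeric(logMoM) * med, screeningMarkers())
}

.mediansAt <- function(curve, week) {
  vapply(screeningMarkers(), function(mk)
    medianLevel(curve, mk, week), numeric(1))
}

#' Generate a synthetic screening cohort
#'
#' Draws a complete cohort from a \linkS4class{SimulationConfig}: per group,
#' log10 MoM vectors from the group's multivariate Gaussian, converted to raw
#' concentrations against the configured control median curve; maternal age
#' uniform over the configured range, weight lognormal around the configured
#' median, gestational week uniform over the configured weeks. The entire
#' draw is reproducible from \code{config@seed}. Levels are rounded to 4
#' decimals (age 2, weight 1) so that cohort CSVs round-trip byte-identically.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A \linkS4class{ScreeningCohort}; the generating curve and config
#'   are stored in \code{metadata()} under \code{median_curve} and
#'   \code{sim_config}.
#' @examples
#' coh <- generateCohort(simulationConfig(
#'   groupSizes = c(control = 20, T21 = 5, T18 = 5), seed = 7))
#' table(subjectGroups(coh))
#' @importFrom S4Vectors metadata `metadata<-`
#' @export
generateCohort <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  groups <- names(config@groupSizes)[config@groupSizes > 0]
  lv <- list(); grp <- list(); age <- list(); wt <- list(); wk <- list()
  for (g in groups) {
    n <- config@groupSizes[[g]]
    lm <- sampleLogMoM(config@groupParams[[g]], n, seed = NULL)
    week <- sample(seq(config@weekRange[1], config@weekRange[2]), n,
                   replace = TRUE)
    lev <- reconstructLevels(lm, config@medianCurve, week)
    lv[[g]] <- round(lev, 4)
    grp[[g]] <- rep(g, n)
    age[[g]] <- round(stats::runif(n, config@ageRange[1], config@ageRange[2]), 2)
    wt[[g]] <- round(stats::rlnorm(n, log(config@weightMedian),
                                   config@weightSdLog), 1)
    wk[[g]] <- week
  }
  levels <- t(do.call(rbind, lv))
  coh <- ScreeningCohort(levels,
                         group = unlist(grp, use.names = FALSE),
                         age = unlist(age, use.names = FALSE),
                         weight = unlist(wt, use.names = FALSE),
                         gestationalWeek = unlist(wk, use.names = FALSE))
  S4Vectors::metadata(coh)$median_curve <- config@medianCurve
  S4Vectors::metadata(coh)$sim_config <- config
  coh
}

#' Read a SimulationConfig from JSON
#'
#' Accepts the schema of the bundled \code{params_table2.json} with optional
#' top-level \code{seed}.
#'
#' @param path JSON path.
#' @param seed Seed overriding any value in the file (optional).
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfigFromJson <- function(path, seed = NULL) {
  params <- table2Params(path)
  demo <- attr(params, "demographics")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(seed)) seed <- if (!is.null(raw$seed)) raw$seed else 1L
  simulationConfig(
    groupSizes = attr(params, "group_sizes"),
    groupParams = params[names(params)],
    medianCurve = medianCurve(attr(params, "control_medians")),
    ageRange = as.numeric(demo$age_range),
    weightMedian = as.numeric(demo$weight_median_kg),
    weightSdLog = as.numeric(demo$weight_sdlog),
    weekRange = as.integer(demo$week_range),
    seed = seed)
}
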