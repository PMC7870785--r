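#' ScreeningCohort: a serum-marker screening cohort
#'
#' An S4 container for a second-trimester screening cohort, extending
#' \linkS4class{SummarizedExperiment}. Rows are the four serum markers
#' (\code{\link{screeningMarkers}}), columns are pregnancies. The
#' \code{"levels"} assay holds raw marker concentrations (sHLA-G in U/ml, the
#' triple-test analytes in whatever concentration unit the assay reports —
#' units cancel in MoM). \code{\link{computeMoM}} adds \code{"mom"} and
#' \code{"log10_mom"} assays. Column data carry \code{group} (control / T21 /
#' T18), \code{age} (years), \code{weight} (kg) and \code{gestational_week}
#' (integer, 15--19).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no additional slots.
#' @seealso \code{\link{ScreeningCohort}} (constructor),
#'   \code{\link{generateCohort}}, \code{\link{computeMoM}}
#' @aliases ScreeningCohort-class
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass ScreeningCohort
setClass("ScreeningCohort", contains = "SummarizedExperiment")

setValidity("ScreeningCohort", function(object) {
  msg <- character()
  if (!identical(rownames(object), screeningMarkers()))
    msg <- c(msg, paste("rows must be the markers",
                        paste(screeningMarkers(), collapse = ", ")))
  if (!"levels" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'levels' assay is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("group", "age", "weight", "gestational_week")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (!length(msg) && ncol(object) > 0) {
    lv <- SummarizedExperiment::assay(object, "levels")
    if (any(!is.finite(lv)) || any(lv <= 0))
      msg <- c(msg, "all marker levels must be finite and strictly positive")
    if (!all(as.character(cd$group) %in% screeningGroups()))
      msg <- c(msg, "group labels must be control, T21 or T18")
    wk <- cd$gestational_week
    if (any(wk != as.integer(wk)) || any(wk < 15L) || any(wk > 19L))
      msg <- c(msg, "gestational_week must be an integer in 15..19")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ScreeningCohort
#'
#' @param levels Numeric matrix of marker concentrations, 4 markers (rows, in
#'   \code{\link{screeningMarkers}} order) by n subjects (columns), strictly
#'   positive.
#' @param group Character or factor of group labels (\code{"control"},
#'   \code{"T21"}, \code{"T18"}), one per subject.
#' @param age Maternal ages in years.
#' @param weight Maternal weights in kg.
#' @param gestationalWeek Integer gestational weeks (15--19).
#' @param subjectId Optional subject identifiers; defaults to
#'   \code{S0001, S0002, ...}.
#'
#' @return A \linkS4class{ScreeningCohort}.
#' @examples
#' lv <- matrix(c(30, 20, 4, 106.3), nrow = 4,
#'              dimnames = list(screeningMarkers(), "S0001"))
#' ScreeningCohort(lv, group = "control", age = 28, weight = 54.5,
#'                 gestationalWeek = 16L)
#' @importFrom S4Vectors DataFrame
#' @export
ScreeningCohort <- function(levels, group, age, weight, gestationalWeek,
                            subjectId = NULL) {
  levels <- as.matrix(levels)
  if (nrow(levels) != 4L)
    stop("'levels' must have one row per marker (4 rows)")
  rownames(levels) <- screeningMarkers()
  n <- ncol(levels)
  if (is.null(subjectId)) subjectId <- sprintf("S%04d", seq_len(n))
  colnames(levels) <- subjectId
  group <- factor(as.character(group), levels = screeningGroups())
  cd <- S4Vectors::DataFrame(
    group = group,
    age = as.numeric(age),
    weight = as.numeric(weight),
    gestational_week = as.integer(gestationalWeek),
    row.names = subjectId
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(levels = levels), colData = cd)
  methods::new("ScreeningCohort", se)
}

#' @describeIn ScreeningCohort raw marker concentration matrix (markers x
#'   subjects).
#' @param x,object A \linkS4class{ScreeningCohort}.
#' @export
markerLevels <- function(x) SummarizedExperiment::assay(x, "levels")

#' @describeIn ScreeningCohort MoM matrix; error if \code{\link{computeMoM}}
#'   has not been run.
#' @export
momValues <- function(x) {
  if (!"mom" %in% SummarizedExperiment::assayNames(x))
    stop("no 'mom' assay: run computeMoM() first")
  SummarizedExperiment::assay(x, "mom")
}

#' @describeIn ScreeningCohort log10 MoM matrix; error if
#'   \code{\link{computeMoM}} has not been run.
#' @export
log10MoM <- function(x) {
  if (!"log10_mom" %in% SummarizedExperiment::assayNames(x))
    stop("no 'log10_mom' assay: run computeMoM() first")
  SummarizedExperiment::assay(x, "log10_mom")
}

#' @describeIn ScreeningCohort group factor (control/T21/T18).
#' @export
subjectGroups <- function(x) SummarizedExperiment::colData(x)$group

#' @describeIn ScreeningCohort integer gestational weeks.
#' @export
gestationalWeeks <- function(x) SummarizedExperiment::colData(x)$gestational_week

#' @describeIn ScreeningCohort maternal ages (years).
#' @export
maternalAge <- function(x) SummarizedExperiment::colData(x)$age

#' @describeIn ScreeningCohort maternal weights (kg).
#' @export
maternalWeight <- function(x) SummarizedExperiment::colData(x)$weight

#' @describeIn ScreeningCohort compact display.
#' @export
setMethod("show", "ScreeningCohort", function(object) {
  tab <- table(subjectGroups(object))
  cat("ScreeningCohort with", ncol(object), "subjects (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n")
  cat("  markers:", paste(rownames(object), collapse = ", "), "\n")
  cat("  assays :", paste(SummarizedExperiment::assayNames(object),
                          collapse = ", "), "\n")
  wk <- range(gestationalWeeks(object))
  if (ncol(object)) cat("  weeks  :", wk[1], "-", wk[2], "\n")
  invisible(NULL)
})
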