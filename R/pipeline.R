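#' Write / read a cohort as CSV
#'
#' Schema: \code{subject_id,group,age,weight,gestational_week,afp,free_bhcg,
#' ue3,shla_g}, UTF-8, '.' decimal separator. Reading validates the header,
#' group labels, numeric fields, positivity of levels and the gestational
#' week range, reporting the offending line on failure; writing a cohort
#' produced by \code{\link{generateCohort}} round-trips byte-identically.
#'
#' @param cohort A \linkS4class{ScreeningCohort}.
#' @param path CSV path.
#' @return \code{writeCohortCsv}: \code{path}, invisibly.
#'   \code{readCohortCsv}: a \linkS4class{ScreeningCohort}.
#' @examples
#' coh <- generateCohort(simulationConfig(
#'   groupSizes = c(control = 5, T21 = 2, T18 = 2), seed = 5))
#' f <- tempfile(fileext = ".csv")
#' writeCohortCsv(coh, f)
#' coh2 <- readCohortCsv(f)
#' @export
writeCohortCsv <- function(cohort, path) {
  lv <- markerLevels(cohort)
  df <- data.frame(
    subject_id = colnames(cohort),
    group = as.character(subjectGroups(cohort)),
    age = maternalAge(cohort),
    weight = maternalWeight(cohort),
    gestational_week = gestationalWeeks(cohort),
    afp = lv["afp", ], free_bhcg = lv["free_bhcg", ],
    ue3 = lv["ue3", ], shla_g = lv["shla_g", ],
    row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  header <- c("subject_id", "group", "age", "weight", "gestational_week",
              "afp", "free_bhcg", "ue3", "shla_g")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!identical(colnames(df), header))
    stop("unexpected cohort CSV header in ", path, "; expected: ",
         paste(header, collapse = ","))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    if (!df$group[i] %in% screeningGroups())
      stop("line ", line, ": unknown group label '", df$group[i], "'")
    lv <- as.numeric(df[i, screeningMarkers()])
    if (any(is.na(lv)) || any(lv <= 0))
      stop("line ", line, ": marker levels must be positive numbers")
    wk <- df$gestational_week[i]
    if (is.na(wk) || wk != as.integer(wk) || wk < 15 || wk > 19)
      stop("line ", line, ": gestational_week must be an integer in 15..19")
  }
  ScreeningCohort(t(as.matrix(df[, screeningMarkers()])),
                  group = df$group, age = df$age, weight = df$weight,
                  gestationalWeek = df$gestational_week,
                  subjectId = df$subject_id)
}

# Polynomial rolling hash of a string, 8 hex digits; provenance stamp for
# report rows (not cryptographic).
.configHash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' PipelineConfig: one end-to-end screening analysis
#'
#' Bundles a \linkS4class{SimulationConfig} with the analysis choices: the
#' weight-correction model, the prior model, whether the likelihood ratio
#' uses the inter-marker correlations, and the control false-positive rate at
#' which screen-positive cutoffs are set.
#'
#' @slot simulation \linkS4class{SimulationConfig}.
#' @slot weightModelType "identity" or "reciprocal".
#' @slot prior \linkS4class{PriorModel}.
#' @slot useCorrelations Logical.
#' @slot targetFpr False-positive rate in (0, 1).
#' @aliases PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
  simulation = "SimulationConfig", weightModelType = "character",
  prior = "PriorModel", useCorrelations = "logical", targetFpr = "numeric"))

setValidity("PipelineConfig", function(object) {
  if (object@targetFpr <= 0 || object@targetFpr >= 1)
    return("targetFpr must be in (0, 1)")
  if (!object@weightModelType %in% c("identity", "reciprocal"))
    return("weightModelType must be 'identity' or 'reciprocal'")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param simulation A \linkS4class{SimulationConfig} (default: the bundled
#'   reference-population configuration).
#' @param weightModelType "identity" (default) or "reciprocal".
#' @param prior A \linkS4class{PriorModel}.
#' @param useCorrelations Use correlated likelihood ratios (default FALSE).
#' @param targetFpr Control false-positive rate for screen-positive cutoffs
#'   (default 0.05).
#' @param seed Convenience override of \code{simulation@seed}.
#' @return A \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           weightModelType = "identity",
                           prior = priorModel(), useCorrelations = FALSE,
                           targetFpr = 0.05, seed = NULL) {
  if (!is.null(seed)) simulation@seed <- as.integer(seed)
  methods::new("PipelineConfig", simulation = simulation,
               weightModelType = weightModelType, prior = prior,
               useCorrelations = useCorrelations,
               targetFpr = as.numeric(targetFpr))
}

#' Run the full screening pipeline
#'
#' simulate -> fit control medians -> MoM -> (optional weight adjustment) ->
#' group summaries -> risk scoring -> per-marker and risk-score evaluation,
#' writing a report bundle to \code{outputDir}:
#' \itemize{
#'   \item \code{cohort.csv} -- the simulated cohort;
#'   \item \code{mom.csv} -- long-format MoM table
#'     (\code{subject_id,marker,mom,log10_mom});
#'   \item \code{group_summary.csv}, \code{correlations.csv},
#'     \code{mann_whitney.csv} -- the distribution report;
#'   \item \code{risk.csv} -- per-subject risk results;
#'   \item \code{evaluation.csv} -- per-marker and combined-risk ROC/Youden
#'     metrics per trisomy;
#'   \item \code{roc_points_<trisomy>_<score>.csv} -- ROC coordinates;
#'   \item \code{run_log.txt} -- seed, config hash, stage timings.
#' }
#' Every report row carries the config hash; rerunning with the same config
#' is byte-identical.
#'
#' @param config A \linkS4class{PipelineConfig}.
#' @param outputDir Output directory (created if missing).
#' @param verbose Print stage progress (default TRUE).
#' @return Invisibly, a list with the cohort, group parameters, risk table
#'   and evaluation table.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(seed = 1)
#' res <- runPipeline(cfg, tempfile("run"))
#' }
#' @export
runPipeline <- function(config, outputDir, verbose = TRUE) {
  methods::validObject(config)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[momscreen] ", ...)
  hash <- .configHash(paste(
    utils::capture.output(utils::str(config, max.level = 3)), collapse = "\n"))
  log <- c(sprintf("momscreen pipeline run"),
           sprintf("seed: %d", config@simulation@seed),
           sprintf("config hash: %s", hash),
           sprintf("target FPR: %g", config@targetFpr),
           sprintf("use correlations: %s", config@useCorrelations),
           sprintf("weight model: %s", config@weightModelType))

  say("simulating cohort")
  cohort <- generateCohort(config@simulation)
  writeCohortCsv(cohort, file.path(outputDir, "cohort.csv"))
  log <- c(log, sprintf("cohort: %d subjects (%s)", ncol(cohort),
                        paste(names(table(subjectGroups(cohort))),
                              table(subjectGroups(cohort)),
                              sep = "=", collapse = ", ")))

  say("fitting control medians and computing MoM")
  curve <- fitMedianCurve(cohort)
  cohort <- computeMoM(cohort, curve)
  if (config@weightModelType == "reciprocal")
    cohort <- weightAdjust(cohort, fitWeightModel(cohort))
  mom <- momValues(cohort); lmom <- log10MoM(cohort)
  momTab <- data.frame(
    subject_id = rep(colnames(cohort), each = 4),
    marker = rep(screeningMarkers(), ncol(cohort)),
    mom = as.vector(mom), log10_mom = as.vector(lmom),
    config_hash = hash, row.names = NULL)
  utils::write.csv(momTab, file.path(outputDir, "mom.csv"),
                   row.names = FALSE, quote = FALSE)

  say("summarizing groups")
  present <- names(which(table(subjectGroups(cohort)) >= 2))
  summ <- groupSummaryTable(cohort, intersect(screeningGroups(), present))
  summ$distribution$config_hash <- hash
  summ$correlations$config_hash <- hash
  utils::write.csv(summ$distribution,
                   file.path(outputDir, "group_summary.csv"),
                   row.names = FALSE, quote = TRUE)
  utils::write.csv(summ$correlations,
                   file.path(outputDir, "correlations.csv"),
                   row.names = FALSE, quote = TRUE)
  if (!is.null(summ$tests)) {
    summ$tests$config_hash <- hash
    utils::write.csv(summ$tests, file.path(outputDir, "mann_whitney.csv"),
                     row.names = FALSE, quote = TRUE)
  }
  params <- lapply(intersect(screeningGroups(), present),
                   function(g) summarizeGroup(cohort, g))
  names(params) <- intersect(screeningGroups(), present)

  trisomies <- intersect(c("T21", "T18"), names(params))
  skipped <- setdiff(c("T21", "T18"), trisomies)
  for (g in skipped) {
    say("group ", g, " empty or too small; evaluation skipped")
    log <- c(log, sprintf("group %s skipped (absent or n < 2)", g))
  }

  risk <- NULL
  if (length(trisomies) && "control" %in% names(params)) {
    say("scoring risks")
    risk <- scoreCohort(cohort, paramsByGroup = params,
                        prior = config@prior, trisomies = trisomies,
                        targetFpr = config@targetFpr,
                        useCorrelations = config@useCorrelations)
    risk$config_hash <- hash
    utils::write.csv(risk, file.path(outputDir, "risk.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  say("evaluating markers and risk scores")
  evalTab <- NULL
  grp <- as.character(subjectGroups(cohort))
  for (tr in trisomies) {
    sel <- grp %in% c("control", tr)
    labs <- as.integer(grp[sel] == tr)
    scoreSets <- stats::setNames(
      lapply(screeningMarkers(), function(mk) mom[mk, sel]),
      screeningMarkers())
    if (!is.null(risk)) {
      rsub <- risk[risk$trisomy == tr, ]
      scoreSets$posterior_risk <- rsub$posterior[sel]
    }
    for (nm in names(scoreSets)) {
      sc <- scoreSets[[nm]]
      roc <- rocCurve(sc, labs)
      yj <- youdenCutoff(roc)
      dr <- detectionRateAtFPR(sc, labs, config@targetFpr)
      row <- data.frame(
        trisomy = tr, score = nm, direction = roc@direction,
        auc = roc@auc, auc_ci_low = roc@ciLow, auc_ci_high = roc@ciHigh,
        auc_p = roc@pValue, cutoff = yj@cutoff,
        sensitivity = yj@sensitivity, specificity = yj@specificity,
        ppv = yj@ppv, npv = yj@npv, plr = yj@plr, nlr = yj@nlr,
        detection_rate_at_target_fpr = dr$detection_rate,
        config_hash = hash, row.names = NULL)
      evalTab <- rbind(evalTab, row)
      pts <- roc@points
      pts$config_hash <- hash
      utils::write.csv(pts, file.path(
        outputDir, sprintf("roc_points_%s_%s.csv", tr, nm)),
        row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(evalTab))
    utils::write.csv(evalTab, file.path(outputDir, "evaluation.csv"),
                     row.names = FALSE, quote = FALSE)

  writeLines(log, file.path(outputDir, "run_log.txt"))
  say("done: ", outputDir)
  invisible(list(cohort = cohort, params = params, risk = risk,
                 evaluation = evalTab, config_hash = hash))
}
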