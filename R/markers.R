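#' Serum marker panel
#'
#' The four-analyte second-trimester panel used throughout the package, in
#' canonical order: alpha-fetoprotein (AFP), free beta-hCG, unconjugated
#' estriol (uE3) and soluble HLA-G (sHLA-G, U/ml).
#'
#' @return Character vector of the four marker identifiers.
#' @examples
#' screeningMarkers()
#' @export
screeningMarkers <- function() {
  c("afp", "free_bhcg", "ue3", "shla_g")
}

#' Human-readable marker labels
#'
#' @return Named character vector mapping marker identifiers to display labels.
#' @examples
#' markerLabels()["shla_g"]
#' @export
markerLabels <- function() {
  c(afp = "AFP", free_bhcg = "free beta-hCG", ue3 = "uE3", shla_g = "sHLA-G")
}

#' Cohort group labels
#'
#' Case-control structure of a screening cohort: euploid controls and the two
#' autosomal trisomies screened for (trisomy 21, Down syndrome; trisomy 18,
#' Edwards syndrome).
#'
#' @return Character vector \code{c("control", "T21", "T18")}.
#' @export
screeningGroups <- function() {
  c("control", "T21", "T18")
}

.checkMarkers <- function(x, what = "object") {
  if (!identical(names(x), screeningMarkers()) &&
      !identical(rownames(x), screeningMarkers())) {
    stop(what, " must be indexed by the markers ",
         paste(screeningMarkers(), collapse = ", "), " in that order",
         call. = FALSE)
  }
  invisible(TRUE)
}
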