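#' MedianCurve: control medians used as the MoM denominator
#'
#' Per-marker medians of unaffected pregnancies. The triple-test analytes
#' (AFP, free beta-hCG, uE3) vary with gestation, so their medians are indexed
#' by integer gestational week (15--19); sHLA-G is not associated with
#' gestational age and carries a single flat median. A marker level divided by
#' the matching median is its multiple of the median (MoM).
#'
#' @slot medians Named list, one element per marker: either a single positive
#'   number (flat median) or a numeric vector named by week
#'   (\code{"15"}..\code{"19"}).
#' @aliases MedianCurve-class
#' @seealso \code{\link{fitMedianCurve}}, \code{\link{computeMoM}},
#'   \code{\link{medianLevel}}
#' @exportClass MedianCurve
setClass("MedianCurve", representation(medians = "list"))

setValidity("MedianCurve", function(object) {
  m <- object@medians
  if (!identical(sort(names(m)), sort(screeningMarkers())))
    return("medians must have one entry per marker")
  for (mk in names(m)) {
    v <- m[[mk]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      return(paste0("medians for ", mk, " must be finite and positive"))
    if (length(v) > 1L && is.null(names(v)))
      return(paste0("week-indexed medians for ", mk, " must be named by week"))
  }
  TRUE
})

#' Construct a MedianCurve
#'
#' @param medians Named list with one element per marker in
#'   \code{\link{screeningMarkers}}: a single number for a flat median, or a
#'   week-named numeric vector for week-indexed medians.
#' @return A \linkS4class{MedianCurve}.
#' @examples
#' medianCurve(list(
#'   afp = c(`15` = 30, `16` = 34, `17` = 39, `18` = 45, `19` = 52),
#'   free_bhcg = c(`15` = 20, `16` = 18, `17` = 17, `18` = 15, `19` = 14),
#'   ue3 = c(`15` = 4, `16` = 4.8, `17` = 5.8, `18` = 7, `19` = 8.4),
#'   shla_g = 106.3))
#' @export
medianCurve <- function(medians) {
  methods::new("MedianCurve", medians = medians[screeningMarkers()])
}

#' Look up the median for a marker (and week)
#'
#' @param curve A \linkS4class{MedianCurve}.
#' @param marker One of \code{\link{screeningMarkers}}.
#' @param week Integer gestational week; ignored for flat markers.
#' @return The median concentration (positive scalar).
#' @export
medianLevel <- function(curve, marker, week = NULL) {
  v <- curve@medians[[marker]]
  if (is.null(v)) stop("unknown marker: ", marker)
  if (length(v) == 1L) return(unname(v))
  if (is.null(week)) stop("marker ", marker, " is week-indexed; 'week' required")
  out <- v[as.character(week)]
  if (any(is.na(out)))
    stop("no median for marker ", marker, " at week ",
         paste(week[is.na(out)], collapse = ", "))
  unname(out)
}

#' Is a marker's median flat (week-independent)?
#' @inheritParams medianLevel
#' @return Logical scalar.
#' @export
isFlatMedian <- function(curve, marker) {
  length(curve@medians[[marker]]) == 1L
}

#' @describeIn medianCurve compact display.
#' @param object A \linkS4class{MedianCurve}.
#' @export
setMethod("show", "MedianCurve", function(object) {
  cat("MedianCurve\n")
  for (mk in screeningMarkers()) {
    v <- object@medians[[mk]]
    if (length(v) == 1L) {
      cat(sprintf("  %-10s flat %.4g\n", mk, unname(v)))
    } else {
      cat(sprintf("  %-10s weeks %s: %s\n", mk,
                  paste(range(as.integer(names(v))), collapse = "-"),
                  paste(signif(unname(v), 4), collapse = ", ")))
    }
  }
  invisible(NULL)
})

#' Serialize / deserialize a MedianCurve as JSON
#'
#' @param curve A \linkS4class{MedianCurve}.
#' @param path File path.
#' @return \code{readMedianCurve} returns a \linkS4class{MedianCurve};
#'   \code{writeMedianCurve} returns \code{path} invisibly.
#' @export
writeMedianCurve <- function(curve, path) {
  jsonlite::write_json(lapply(curve@medians, function(v)
    if (length(v) == 1L) unname(v) else as.list(v)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMedianCurve
#' @export
readMedianCurve <- function(path) {
  raw <- jsonlite::read_json(path)
  medianCurve(lapply(raw, function(v)
    if (is.list(v)) unlist(v) else as.numeric(v)))
}
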