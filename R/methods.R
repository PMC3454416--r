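#' @describeIn EnrichmentResult-class empirical P-value.
setMethod("pValue", "EnrichmentResult", function(x) x@pValue)

#' @describeIn CaseControlResult-class permutation P-value.
setMethod("pValue", "CaseControlResult", function(x) x@pValue)

#' @describeIn EnrichmentResult-class observed in-track point count.
setMethod("observedOverlap", "EnrichmentResult", function(x) x@observedOverlap)

#' @describeIn EnrichmentResult-class null in-track counts, one per draw.
setMethod("nullOverlaps", "EnrichmentResult", function(x) x@nullOverlaps)

#' @describeIn EnrichmentResult-class enrichment ratio on the real data.
setMethod("enrichment", "EnrichmentResult", function(x) x@enrichment)

#' @describeIn foldDifference accessor on a stored result.
setMethod("foldDifference", "CaseControlResult", function(x, ...) x@foldDiff)

#' @describeIn CaseControlResult-class case in-track proportion.
#' @export
caseProportion <- function(x) x@caseProp

#' @describeIn CaseControlResult-class control in-track proportion.
#' @export
controlProportion <- function(x) x@controlProp

.fmt <- function(x) formatC(signif(x, 4), format = "g", digits = 4)

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", object@trackName, "\n")
  cat(sprintf("  points: %d  in track: %d  enrichment: %s\n",
              object@nPoints, object@observedOverlap,
              .fmt(object@enrichment)))
  cat(sprintf("  empirical P: %s  (one-sided greater, %d Monte Carlo draws%s)\n",
              format(object@pValue, digits = 4), object@nMc,
              if (is.na(object@seed)) "" else sprintf(", seed %d", object@seed)))
})

setMethod("show", "CaseControlResult", function(object) {
  cat("CaseControlResult:", object@caseName, "vs", object@controlName, "\n")
  cat(sprintf("  case: %d points, prop in track %s; control: %d points, prop %s\n",
              object@nCase, .fmt(object@caseProp),
              object@nControl, .fmt(object@controlProp)))
  cat(sprintf("  fold difference: %s  permutation P: %s (%d permutations%s)\n",
              .fmt(object@foldDiff), format(object@pValue, digits = 4),
              object@nPerm,
              if (is.na(object@seed)) "" else sprintf(", seed %d", object@seed)))
})

setMethod("show", "SitePartition", function(object) {
  cat(sprintf("SitePartition for group '%s' (threshold %s)\n",
              object@group, format(object@threshold, digits = 6)))
  cat(sprintf("  significant: %d  unique: %d  hyper: %d  hypo: %d  zero-slope: %d\n",
              length(object@significant), length(object@unique),
              length(object@hyper), length(object@hypo), object@nZeroSlope))
  cat(sprintf("  top-%d hyper: %d  top-%d hypo: %d\n",
              object@k, length(object@topKHyper),
              object@k, length(object@topKHypo)))
})

#' @describeIn SitePartition-class extract one subset by name
#'   (\code{"significant"}, \code{"unique"}, \code{"hyper"}, \code{"hypo"},
#'   \code{"topKHyper"}, \code{"topKHypo"}).
#' @param x a \code{SitePartition}.
#' @param subset subset name.
#' @export
siteSubset <- function(x, subset = c("significant", "unique", "hyper",
                                     "hypo", "topKHyper", "topKHypo")) {
  subset <- match.arg(subset)
  slot(x, subset)
}

#' @describeIn EnrichmentResult-class one-row report data.frame
#'   (track_name, n_points, observed_overlap, enrichment, p_value, n_mc,
#'   seed).
setMethod("asReportRow", "EnrichmentResult", function(x, ...) {
  data.frame(track_name = x@trackName,
             n_points = x@nPoints,
             observed_overlap = x@observedOverlap,
             enrichment = x@enrichment,
             p_value = x@pValue,
             n_mc = x@nMc,
             seed = x@seed,
             stringsAsFactors = FALSE)
})

#' @describeIn CaseControlResult-class one-row report data.frame
#'   (case_name, control_name, case/control proportions, fold_difference,
#'   p_value, n_perm, seed).
setMethod("asReportRow", "CaseControlResult", function(x, ...) {
  data.frame(case_name = x@caseName,
             control_name = x@controlName,
             n_case = x@nCase,
             n_control = x@nControl,
             case_prop = x@caseProp,
             control_prop = x@controlProp,
             fold_difference = x@foldDiff,
             p_value = x@pValue,
             n_perm = x@nPerm,
             seed = x@seed,
             stringsAsFactors = FALSE)
})
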