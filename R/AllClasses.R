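#' @import methods
#' @importFrom GenomicRanges GRanges granges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
NULL

#' SitePartition: the derived probe subsets for one age group
#'
#' Holds every probe subset derived from a probe-association table for a
#' single age group: all significant sites, sites unique to the group,
#' the hyper-/hypo-methylated split of the unique sites, and the top-k
#' most significant sites of each direction. All subsets are width-1
#' \link[GenomicRanges]{GRanges} point sets carrying the probe annotation
#' columns.
#'
#' @slot group age-group label (e.g. \code{"adult"}).
#' @slot significant sites with association P strictly below \code{threshold}.
#' @slot unique significant sites not significant in any other group.
#' @slot hyper unique sites with positive methylation-vs-age slope.
#' @slot hypo unique sites with negative slope.
#' @slot topKHyper the k most significant hyper sites (see [topKSites()]).
#' @slot topKHypo the k most significant hypo sites.
#' @slot threshold the significance cutoff applied.
#' @slot k the top-k size requested.
#' @slot nZeroSlope number of unique sites with slope exactly 0, which
#'   belong to neither direction.
#'
#' @seealso [sitePartition()]
#' @export
setClass("SitePartition",
  representation(
    group = "character",
    significant = "GRanges",
    unique = "GRanges",
    hyper = "GRanges",
    hypo = "GRanges",
    topKHyper = "GRanges",
    topKHypo = "GRanges",
    threshold = "numeric",
    k = "integer",
    nZeroSlope = "integer"
  )
)

setValidity("SitePartition", function(object) {
  msg <- character()
  if (length(object@group) != 1L) msg <- c(msg, "group must be length 1")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1)
    msg <- c(msg, "threshold must be a single value in (0, 1)")
  nU <- length(object@unique)
  if (nU > length(object@significant))
    msg <- c(msg, "unique set larger than significant set")
  if (length(object@hyper) + length(object@hypo) + object@nZeroSlope != nU)
    msg <- c(msg, "hyper + hypo + zero-slope must partition the unique set")
  if (length(object@topKHyper) > object@k ||
      length(object@topKHypo) > object@k)
    msg <- c(msg, "top-k sets larger than k")
  if (length(msg)) msg else TRUE
})

#' EnrichmentResult: a global Monte Carlo enrichment test outcome
#'
#' Result of [mcEnrichmentTest()]: the observed in-track point overlap,
#' the enrichment ratio on the real data, the null overlap samples from
#' track randomization, and the one-sided empirical P-value.
#'
#' @slot trackName label used in reports.
#' @slot nPoints number of probe points tested.
#' @slot observedOverlap number of points inside the track.
#' @slot enrichment the enrichment ratio (see [enrichmentRatio()]).
#' @slot nullOverlaps integer vector of in-track counts under the null,
#'   one per Monte Carlo draw.
#' @slot pValue one-sided (greater) add-one empirical P.
#' @slot nMc number of Monte Carlo draws.
#' @slot seed RNG seed used (NA if none supplied).
#'
#' @seealso [mcEnrichmentTest()], [empiricalP()]
#' @export
setClass("EnrichmentResult",
  representation(
    trackName = "character",
    nPoints = "integer",
    observedOverlap = "integer",
    enrichment = "numeric",
    nullOverlaps = "integer",
    pValue = "numeric",
    nMc = "integer",
    seed = "integer"
  )
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (length(object@nullOverlaps) != object@nMc)
    msg <- c(msg, "nullOverlaps must have length nMc")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (object@enrichment < 0)
    msg <- c(msg, "enrichment must be non-negative")
  if (object@observedOverlap < 0 || object@observedOverlap > object@nPoints)
    msg <- c(msg, "observedOverlap must lie in [0, nPoints]")
  if (length(msg)) msg else TRUE
})

#' CaseControlResult: a label-permutation comparison outcome
#'
#' Result of [labelPermutationTest()]: the in-track overlap proportions of
#' the case and control point sets, their fold difference, and the
#' one-sided permutation P-value for case overlap exceeding control.
#'
#' @slot caseName,controlName labels used in reports.
#' @slot nCase,nControl set sizes.
#' @slot caseProp,controlProp in-track overlap proportions.
#' @slot foldDiff ratio caseProp / controlProp (Inf when controlProp is 0
#'   and caseProp > 0; NaN when both are 0).
#' @slot pValue one-sided (greater) add-one empirical P.
#' @slot nPerm number of label permutations.
#' @slot seed RNG seed used (NA if none supplied).
#'
#' @seealso [labelPermutationTest()], [foldDifference()]
#' @export
setClass("CaseControlResult",
  representation(
    caseName = "character",
    controlName = "character",
    nCase = "integer",
    nControl = "integer",
    caseProp = "numeric",
    controlProp = "numeric",
    foldDiff = "numeric",
    pValue = "numeric",
    nPerm = "integer",
    seed = "integer"
  )
)

setValidity("CaseControlResult", function(object) {
  msg <- character()
  ok01 <- function(x) x >= 0 && x <= 1
  if (!ok01(object@caseProp) || !ok01(object@controlProp))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (!is.nan(object@foldDiff) && object@foldDiff < 0)
    msg <- c(msg, "foldDiff must be non-negative (or NaN when undefined)")
  if (length(msg)) msg else TRUE
})
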