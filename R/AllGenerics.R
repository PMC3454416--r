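#' @rdname EnrichmentResult-class
#' @param x a result object.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("observedOverlap", function(x) standardGeneric("observedOverlap"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("nullOverlaps", function(x) standardGeneric("nullOverlaps"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("enrichment", function(x) standardGeneric("enrichment"))

#' Fold difference in in-track overlap between case and control sets
#'
#' The ratio of the case set's in-track overlap proportion to the control
#' set's. Dispatches either on two point sets plus a merged track
#' (computation) or on a [CaseControlResult-class] (accessor).
#'
#' @param x a width-1 \link[GenomicRanges]{GRanges} of case points, or a
#'   \code{CaseControlResult}.
#' @param ... \code{control} (width-1 GRanges) and \code{track} (merged
#'   GRanges) when computing.
#' @return A single ratio: \code{Inf} when the control proportion is 0 and
#'   the case proportion positive; \code{NaN} when both proportions are 0.
#' @examples
#' genome <- genomeAssembly(c(chr1 = 1000L))
#' track <- mergeTrack(asTrack("chr1", 100, 200, genome))
#' case <- asPoints("chr1", c(150L, 160L, 170L, 180L, 500L:505L), genome)
#' control <- asPoints("chr1", c(150L, 151L, 300L:317L), genome)
#' foldDifference(case, control, track)  # (4/10)/(2/20) = 4
#' @export
setGeneric("foldDifference", function(x, ...) standardGeneric("foldDifference"))

#' One-row report representation of a result object
#'
#' @param x a result object.
#' @param ... unused.
#' @return A one-row \code{data.frame} mirroring a report table row.
#' @export
setGeneric("asReportRow", function(x, ...) standardGeneric("asReportRow"))
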