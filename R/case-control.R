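#' @describeIn foldDifference compute the fold difference of two point
#'   sets' in-track proportions.
#' @export
setMethod("foldDifference", "GRanges", function(x, control, track) {
  case <- x
  if (length(case) < 1L || length(control) < 1L)
    stop("case and control sets must be non-empty")
  .assertMerged(track)
  pc <- pointsInTrack(case, track) / length(case)
  pk <- pointsInTrack(control, track) / length(control)
  if (pk == 0) {
    if (pc == 0) return(NaN)  # undefined: neither set touches the track
    return(Inf)
  }
  pc / pk
})

#' Label-permutation test of case vs control in-track overlap
#'
#' Compares the in-track overlap of two disjoint point sets (e.g.
#' hyper- vs hypo-methylated probes) by randomly permuting the
#' case/control labels over the pooled points, preserving group sizes.
#' The statistic is the case in-track count (equivalent to the case
#' proportion at fixed |case|); the P-value is one-sided (greater) with
#' the add-one convention, asking whether case overlap exceeds control.
#'
#' @param case,control disjoint width-1 \link[GenomicRanges]{GRanges}
#'   point sets (no shared positions).
#' @param track merged \link[GenomicRanges]{GRanges}.
#' @param nPerm number of label permutations (convention: 50,000).
#' @param seed optional integer seed; recorded in the result.
#' @param caseName,controlName labels carried into reports.
#' @return A [CaseControlResult-class].
#' @examples
#' genome <- genomeAssembly(c(c1 = 10000L))
#' track <- mergeTrack(asTrack("c1", 1000, 2000, genome))
#' hyper <- asPoints("c1", c(1100L, 1200L, 1300L, 9000L), genome)
#' hypo <- asPoints("c1", c(3000L, 4000L, 5000L, 1500L), genome)
#' labelPermutationTest(hyper, hypo, track, nPerm = 500L, seed = 1L)
#' @export
labelPermutationTest <- function(case, control, track, nPerm = 50000L,
                                 seed = NULL, caseName = "case",
                                 controlName = "control") {
  if (length(case) < 1L || length(control) < 1L)
    stop("case and control sets must be non-empty")
  .assertMerged(track)
  if (sum(countOverlaps(case, control, type = "equal")) > 0)
    stop("case and control sets share points; they must be disjoint")
  if (nPerm < 1L) stop("nPerm must be >= 1")
  nCase <- length(case)
  nPool <- nCase + length(control)
  inTrack <- c(overlapsAny(case, track), overlapsAny(control, track))
  observed <- sum(inTrack[seq_len(nCase)])
  doPerms <- function() {
    vapply(seq_len(nPerm), function(i)
      sum(inTrack[sample.int(nPool, nCase)]), integer(1))
  }
  perms <- if (is.null(seed)) doPerms() else withr::with_seed(seed, doPerms())
  pc <- observed / nCase
  pk <- sum(inTrack[-seq_len(nCase)]) / length(control)
  fold <- if (pk == 0) { if (pc == 0) NaN else Inf } else pc / pk
  new("CaseControlResult",
      caseName = caseName,
      controlName = controlName,
      nCase = as.integer(nCase),
      nControl = length(control),
      caseProp = pc,
      controlProp = pk,
      foldDiff = fold,
      pValue = empiricalP(observed, perms),
      nPerm = as.integer(nPerm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Exhaustive label-permutation P-value
#'
#' Enumerates every assignment of case labels over the pooled points and
#' returns the exact proportion of assignments whose case in-track count
#' is at least the observed one. Feasible only for small pooled sizes;
#' serves as an independent check of [labelPermutationTest()].
#'
#' @inheritParams labelPermutationTest
#' @return The exact permutation P-value.
#' @export
exactLabelPermutationP <- function(case, control, track) {
  .assertMerged(track)
  nCase <- length(case)
  inTrack <- c(overlapsAny(case, track), overlapsAny(control, track))
  nPool <- length(inTrack)
  if (choose(nPool, nCase) > 1e6)
    stop("pooled size too large for exhaustive enumeration")
  observed <- sum(inTrack[seq_len(nCase)])
  combs <- utils::combn(nPool, nCase)
  stats <- colSums(matrix(inTrack[combs], nrow = nCase))
  mean(stats >= observed)
}
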