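#' One-sided add-one empirical P-value
#'
#' The proportion of null samples equal to or more extreme (greater) than
#' the observed statistic, with the add-one convention
#' \eqn{P = (1 + \#\{null \ge obs\}) / (1 + n)} so the estimate is valid
#' and never 0. With n = 50,000 null samples the smallest reportable P is
#' 1/50,001, which prints as 0.00002 at five decimals.
#'
#' @param observed the observed statistic.
#' @param nullSamples numeric vector of null statistics (length >= 1).
#' @return The empirical P in (0, 1].
#' @examples
#' empiricalP(10, 1:9)       # 0.1
#' @export
empiricalP <- function(observed, nullSamples) {
  if (length(nullSamples) < 1L)
    stop("need at least one null sample")
  if (length(observed) != 1L || is.na(observed))
    stop("observed must be a single number")
  (1 + sum(nullSamples >= observed)) / (1 + length(nullSamples))
}

## Fast in-track point count on a numeric layout (0-based starts, layout
## lens): point p is inside iff some start <= p < start + len. pos must be
## sorted ascending per call; starts ascending by construction.
.countInLayout <- function(pos, starts, lens) {
  if (length(starts) == 0L || length(pos) == 0L) return(0L)
  idx <- findInterval(pos, starts)
  hit <- idx >= 1L
  sum(hit & pos < starts[pmax(idx, 1L)] + lens[pmax(idx, 1L)])
}

#' Monte Carlo test of probe enrichment in a track
#'
#' Tests whether the points fall inside the track more often than expected
#' under a null model in which the point coordinates are held fixed and
#' the track is randomized, preserving its per-chromosome segment-length
#' and internal-gap multisets (see [randomizeTrack()]). The compared
#' statistic is the in-track point count; the P-value is one-sided
#' (greater) with the add-one convention. The enrichment ratio reported is
#' computed on the real data with [enrichmentRatio()].
#'
#' @param points width-1 \link[GenomicRanges]{GRanges} of probe points.
#' @param track merged \link[GenomicRanges]{GRanges}.
#' @param genome optional \link[GenomeInfoDb]{Seqinfo}; defaults to the
#'   track's seqinfo.
#' @param nMc number of Monte Carlo draws (the analysis convention is
#'   50,000; reduce for exploration).
#' @param seed optional integer seed; the result records it and repeated
#'   calls with identical inputs are bit-identical.
#' @param trackName label carried into reports.
#' @return An [EnrichmentResult-class].
#' @examples
#' genome <- genomeAssembly(c(c1 = 10000L))
#' track <- mergeTrack(asTrack("c1", c(1000, 5000), c(1500, 5500), genome))
#' pts <- asPoints("c1", c(1100L, 1200L, 5100L, 8000L), genome)
#' mcEnrichmentTest(pts, track, nMc = 200L, seed = 1L)
#' @export
mcEnrichmentTest <- function(points, track, genome = seqinfo(track),
                             nMc = 50000L, seed = NULL,
                             trackName = "track") {
  if (nMc < 1L) stop("nMc must be >= 1")
  .assertMerged(track)
  observed <- pointsInTrack(points, track)
  enr <- enrichmentRatio(points, track, genome)
  geo <- .trackGeometry(track)
  # sorted 0-based point positions per chromosome, aligned with geo; a
  # chromosome with points but no track segment can never contribute
  posBy <- lapply(geo, function(g) {
    p <- start(points)[as.character(seqnames(points)) == g$chrom] - 1L
    sort(p)
  })
  doDraws <- function() {
    vapply(seq_len(nMc), function(i) {
      tot <- 0L
      for (j in seq_along(geo)) {
        g <- geo[[j]]
        lay <- .randomizeLayout(g$lens, g$gaps, g$chromLen)
        tot <- tot + .countInLayout(posBy[[j]], lay$starts, lay$lens)
      }
      tot
    }, integer(1))
  }
  nulls <- if (is.null(seed)) doDraws() else withr::with_seed(seed, doDraws())
  new("EnrichmentResult",
      trackName = trackName,
      nPoints = length(points),
      observedOverlap = as.integer(observed),
      enrichment = enr,
      nullOverlaps = as.integer(nulls),
      pValue = empiricalP(observed, nulls),
      nMc = as.integer(nMc),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
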