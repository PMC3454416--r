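#' @importFrom GenomicRanges GRanges reduce trim start end width seqnames
#'   countOverlaps findOverlaps
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqinfo<- seqlengths seqlevels
#'   seqnames genome
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats runif
NULL

## Coordinate conventions
## ----------------------
## All on-disk formats are 0-based, half-open (BED / chrom.sizes dialects).
## In memory everything is a GRanges (1-based, closed), converted at I/O:
## a BED interval [s, e) maps to GRanges start = s + 1, end = e; an array
## probe at 0-based first base position p maps to the width-1 range
## [p + 1, p + 1]. Strand is ignored throughout.

#' Construct a genome assembly
#'
#' A genome here is just a set of named chromosome lengths, represented as
#' a \link[GenomeInfoDb]{Seqinfo}. Every track and point set carries it so
#' that bounds are checked on construction and the total genome length is
#' available as the enrichment-ratio denominator.
#'
#' @param chromLengths named integer vector, chromosome name -> length (bp).
#' @param name assembly label (free text).
#' @return A \link[GenomeInfoDb]{Seqinfo}.
#' @examples
#' genomeAssembly(c(chr1 = 1e6, chr2 = 5e5), name = "toy")
#' @export
genomeAssembly <- function(chromLengths, name = "custom") {
  if (is.null(names(chromLengths)) || anyDuplicated(names(chromLengths)))
    stop("chromLengths must have unique chromosome names")
  if (any(chromLengths <= 0) || any(is.na(chromLengths)))
    stop("all chromosome lengths must be positive")
  Seqinfo(seqnames = names(chromLengths),
          seqlengths = as.integer(chromLengths),
          isCircular = rep(FALSE, length(chromLengths)),
          genome = name)
}

#' @rdname genomeAssembly
#' @param genome a \link[GenomeInfoDb]{Seqinfo}.
#' @export
totalGenomeLength <- function(genome) {
  sum(as.numeric(seqlengths(genome)))
}

#' Read / write a chrom.sizes genome file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @param name assembly label for the returned object.
#' @return \code{readGenome}: a \link[GenomeInfoDb]{Seqinfo}.
#' @export
readGenome <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("%s: line %d: expected 2 tab-separated fields", path, bad[1]))
  chroms <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(len) | len <= 0 | len != floor(len))
  if (length(bad))
    stop(sprintf("%s: line %d: length must be a positive integer", path, bad[1]))
  genomeAssembly(stats::setNames(len, chroms), name = name)
}

#' @rdname readGenome
#' @param genome a \link[GenomeInfoDb]{Seqinfo} to write.
#' @export
writeGenome <- function(genome, path) {
  writeLines(paste(seqlevels(genome), seqlengths(genome), sep = "\t"), path)
  invisible(path)
}

#' Build tracks and point sets from 0-based coordinates
#'
#' Convenience constructors converting 0-based half-open coordinates (the
#' on-disk convention) into bounds-checked GRanges.
#'
#' @param chrom chromosome name(s), recycled.
#' @param start,end 0-based half-open interval bounds.
#' @param genome a \link[GenomeInfoDb]{Seqinfo}; construction fails if any
#'   coordinate exceeds a chromosome bound or names a missing chromosome.
#' @return A \link[GenomicRanges]{GRanges} (width-1 for \code{asPoints}).
#' @export
asTrack <- function(chrom, start, end, genome) {
  if (any(start < 0) || any(end <= start))
    stop("need 0 <= start < end")
  .checkChroms(chrom, genome)
  # .checkBounds() raises the definitive error; the constructor's own
  # out-of-bound warning would be redundant noise
  gr <- suppressWarnings(GRanges(chrom, IRanges(start + 1L, end),
                                 seqinfo = genome))
  .checkBounds(gr)
  gr
}

#' @rdname asTrack
#' @param pos 0-based point positions.
#' @export
asPoints <- function(chrom, pos, genome) {
  if (any(pos < 0)) stop("positions must be >= 0")
  .checkChroms(chrom, genome)
  gr <- suppressWarnings(GRanges(chrom, IRanges(pos + 1L, width = 1L),
                                 seqinfo = genome))
  .checkBounds(gr)
  gr
}

.checkChroms <- function(chrom, genome) {
  missing <- setdiff(unique(chrom), seqlevels(genome))
  if (length(missing))
    stop(sprintf("chromosome '%s' outside genome bounds (not defined)",
                 missing[1]))
  invisible(chrom)
}

.checkBounds <- function(gr) {
  sl <- seqlengths(seqinfo(gr))[as.character(seqnames(gr))]
  bad <- which(is.na(sl) | end(gr) > sl | start(gr) < 1L)
  if (length(bad))
    stop(sprintf("interval %d (%s:%d-%d) outside chromosome bounds",
                 bad[1], as.character(seqnames(gr))[bad[1]],
                 start(gr)[bad[1]] - 1L, end(gr)[bad[1]]))
  invisible(gr)
}

#' Merge a track to its disjoint sorted union
#'
#' Collapses overlapping and book-ended intervals so no base pair is
#' counted twice in coverage or overlap statistics. All overlap, coverage
#' and randomization operations require a merged track.
#'
#' @param track a \link[GenomicRanges]{GRanges}.
#' @return A sorted GRanges whose ranges are pairwise disjoint and
#'   non-adjacent per chromosome, covering the same base pairs.
#' @examples
#' genome <- genomeAssembly(c(c1 = 1000L))
#' mergeTrack(asTrack("c1", c(100, 150), c(200, 300), genome))
#' @export
mergeTrack <- function(track) {
  .checkBounds(track)
  reduce(granges(track))
}

#' @rdname mergeTrack
#' @export
isMergedTrack <- function(track) {
  if (length(track) == 0L) return(TRUE)
  r <- reduce(granges(track))
  # reduce() output is sorted, disjoint and non-adjacent; a merged track
  # must equal it element for element (so unsorted input fails too)
  length(r) == length(track) &&
    identical(as.character(seqnames(r)), as.character(seqnames(track))) &&
    identical(start(r), start(track)) &&
    identical(end(r), end(track))
}

.assertMerged <- function(track, what = "track") {
  if (!isMergedTrack(track))
    stop(what, " must be merged (see mergeTrack())")
  invisible(track)
}

#' Extend every interval by a flank and clamp to chromosome bounds
#'
#' Grows each interval by \code{flank} bp on both sides (the +/- 2 kb gene
#' extension used for bivalent gene regions), truncating at position 0 and
#' at the chromosome length. The result is not merged.
#'
#' @param track a \link[GenomicRanges]{GRanges} with seqlengths set.
#' @param flank non-negative flank in bp.
#' @return A GRanges with the same metadata columns.
#' @export
extendAndClamp <- function(track, flank) {
  if (flank < 0) stop("flank must be >= 0")
  .checkBounds(track)
  suppressWarnings(trim(track + as.integer(flank)))
}

#' Count points falling inside a merged track
#'
#' A point at 0-based position p is inside \code{[start, end)} iff
#' \code{start <= p < end}. Duplicated points each count.
#'
#' @param points width-1 \link[GenomicRanges]{GRanges}.
#' @param track merged \link[GenomicRanges]{GRanges}.
#' @return Integer count of points inside the track union.
#' @export
pointsInTrack <- function(points, track) {
  .assertMerged(track)
  sum(overlapsAny(points, track))
}

#' Total covered base pairs of a merged track
#'
#' @inheritParams pointsInTrack
#' @return Total bp covered.
#' @export
trackCoverageBp <- function(track) {
  .assertMerged(track)
  sum(as.numeric(width(track)))
}

#' Enrichment ratio of point probes in a track
#'
#' The ratio of the proportion of probe coordinates covered by the track
#' to the proportion of non-probe genome coordinates covered by the track:
#' with n points, k of them inside the track, C covered bp and G total
#' genome bp,
#' \deqn{E = \frac{k/n}{(C-k)/(G-n)}.}
#' Each probe occupies exactly 1 bp, so in-track probes are removed from
#' the non-probe numerator and all probes from its denominator.
#'
#' @inheritParams pointsInTrack
#' @param genome optional \link[GenomeInfoDb]{Seqinfo}; defaults to the
#'   seqinfo carried by \code{track}.
#' @return The enrichment ratio; 0 when no point is in the track; Inf when
#'   the track consists only of probe positions (C - k = 0 with k > 0).
#' @examples
#' genome <- genomeAssembly(c(c1 = 1000L))
#' track <- mergeTrack(asTrack("c1", 100, 200, genome))
#' pts <- asPoints("c1", c(150L, 500L, 700L), genome)
#' enrichmentRatio(pts, track, genome)  # (1/3)/(99/997)
#' @export
enrichmentRatio <- function(points, track, genome = seqinfo(track)) {
  n <- length(points)
  if (n < 1L) stop("need at least one point")
  .assertMerged(track)
  G <- totalGenomeLength(genome)
  if (G <= n) stop("genome length must exceed the number of points")
  k <- pointsInTrack(points, track)
  if (k == 0L) return(0)
  C <- trackCoverageBp(track)
  if (C - k <= 0) return(Inf)
  (k / n) / ((C - k) / (G - n))
}

## Numeric randomization core, shared by randomizeTrack() and the Monte
## Carlo loop in mcEnrichmentTest(). Works in 0-based coordinates.
## lens: segment lengths; gaps: k-1 internal gaps (empty when k <= 1);
## chromLen: chromosome length. Both multisets are independently,
## uniformly permuted and the alternating layout is shifted by a leading
## offset uniform on {0, ..., slack}. Returns list(starts, lens) with
## starts 0-based and lens in layout order.
.randomizeLayout <- function(lens, gaps, chromLen) {
  k <- length(lens)
  slack <- chromLen - sum(lens) - sum(gaps)
  if (slack < 0)
    stop("infeasible layout: segments plus gaps exceed chromosome length")
  if (k > 1L) {
    lens <- lens[sample.int(k)]
    if (length(gaps) > 1L) gaps <- gaps[sample.int(length(gaps))]
  }
  offset <- sample.int(slack + 1L, 1L) - 1L
  starts <- offset + cumsum(c(0, if (k > 1L) lens[-k] + gaps else numeric()))
  list(starts = starts, lens = lens)
}

## Per-chromosome segment geometry of a merged track, 0-based.
.trackGeometry <- function(track) {
  chr <- as.character(seqnames(track))
  lapply(split(seq_along(track), factor(chr, levels = unique(chr))),
         function(i) {
           s <- start(track)[i] - 1L
           e <- end(track)[i]
           list(chrom = chr[i[1]],
                lens = e - s,
                gaps = if (length(i) > 1L) s[-1L] - e[-length(i)] else integer(),
                chromLen = seqlengths(seqinfo(track))[[chr[i[1]]]])
         })
}

#' Randomize a track preserving lengths and internal gaps
#'
#' Draws one sample from the track-randomization null model: per
#' chromosome, the multiset of segment lengths and the multiset of gaps
#' between consecutive segments are preserved (each independently,
#' uniformly permuted), the alternating length/gap layout is kept, and the
#' whole layout is shifted by a leading offset drawn uniformly over its
#' feasible range. Segments never move across chromosomes.
#'
#' @param track merged \link[GenomicRanges]{GRanges}.
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return A merged GRanges with the same per-chromosome length and
#'   internal-gap multisets as the input.
#' @export
randomizeTrack <- function(track, seed = NULL) {
  .assertMerged(track)
  if (length(track) == 0L) return(track)
  geo <- .trackGeometry(track)
  doDraw <- function() {
    layouts <- lapply(geo, function(g)
      .randomizeLayout(g$lens, g$gaps, g$chromLen))
    gr <- GRanges(
      rep(vapply(geo, `[[`, "", "chrom"),
          vapply(layouts, function(l) length(l$starts), 1L)),
      IRanges(start = unlist(lapply(layouts, `[[`, "starts"),
                             use.names = FALSE) + 1L,
              width = unlist(lapply(layouts, `[[`, "lens"),
                             use.names = FALSE)),
      seqinfo = seqinfo(track))
    sort(gr)
  }
  if (is.null(seed)) doDraw() else withr::with_seed(seed, doDraw())
}
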