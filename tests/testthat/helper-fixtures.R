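suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

toyGenome <- function(lengths = c(c1 = 1000L), name = "toy") {
  genomeAssembly(lengths, name = name)
}

# random merged track: nIntervals raw intervals merged to their union
randomMergedTrack <- function(genome, nIntervals = 10L, maxLen = 50L) {
  chroms <- sample(GenomeInfoDb::seqlevels(genome), nIntervals, replace = TRUE)
  sl <- GenomeInfoDb::seqlengths(genome)[chroms]
  len <- sample.int(maxLen, nIntervals, replace = TRUE)
  start0 <- floor(runif(nIntervals) * (sl - len))
  mergeTrack(asTrack(chroms, start0, start0 + len, genome))
}

randomPoints <- function(genome, n = 20L) {
  chroms <- sample(GenomeInfoDb::seqlevels(genome), n, replace = TRUE)
  sl <- GenomeInfoDb::seqlengths(genome)[chroms]
  asPoints(chroms, floor(runif(n) * sl), genome)
}

# independent oracle: per-point, per-interval scan in 0-based coordinates
bruteForceCount <- function(points, track) {
  pc <- as.character(seqnames(points)); pp <- start(points) - 1L
  tc <- as.character(seqnames(track))
  ts <- start(track) - 1L; te <- end(track)
  hits <- 0L
  for (i in seq_along(points)) {
    inside <- FALSE
    for (j in seq_along(track))
      if (pc[i] == tc[j] && ts[j] <= pp[i] && pp[i] < te[j]) inside <- TRUE
    hits <- hits + inside
  }
  hits
}

# probe GRanges built directly (independent of readProbeTable)
probeSet <- function(genome, chrom, pos, probe_id = sprintf("cg%03d",
                     seq_along(pos)), ...) {
  gr <- asPoints(chrom, pos, genome)
  mcols(gr)$probe_id <- probe_id
  stats <- list(...)   # slope_<g> = ..., p_<g> = ...
  for (nm in names(stats)) mcols(gr)[[nm]] <- stats[[nm]]
  metadata(gr)$groups <- unique(sub("^slope_", "",
    grep("^slope_", names(stats), value = TRUE)))
  gr
}

lengthMultiset <- function(track) {
  lapply(split(width(track), as.character(seqnames(track))), sort)
}

gapMultiset <- function(track) {
  bychr <- split(seq_along(track), as.character(seqnames(track)))
  lapply(bychr, function(i) {
    if (length(i) < 2L) return(integer())
    s <- sort(start(track)[i]); e <- sort(end(track)[i])
    sort(s[-1L] - e[-length(e)])
  })
}
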