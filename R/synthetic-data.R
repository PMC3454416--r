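#' @importFrom stats rlnorm rnorm setNames
NULL

#' Configuration for a synthetic methylation enrichment study
#'
#' Defines a complete simulated study: a genome, a set of bivalent-like
#' gene regions, and a probe-association table in which significant
#' hyper-methylated probes are preferentially placed inside the (flank-
#' extended, merged) gene track with a planted enrichment factor.
#'
#' The planted signal is defined through the placement probability
#' \eqn{q = \min(1, \rho c)}, where c is the merged extended track's
#' genome coverage fraction: a significant hyper probe lands uniformly
#' inside the track with probability q and uniformly outside otherwise,
#' so the expected measured [enrichmentRatio()] is approximately the knob
#' \eqn{\rho} (exactly, up to an O(c) bias term). Hypo-significant and
#' non-significant probes are uniform over the genome.
#'
#' Defaults mirror a 27k-style promoter array study of brain aging:
#' 27,578 probes; 1,792 gene regions extended by +/-2 kb; per-group
#' significant counts (hyper/hypo) of 20/83 fetal, 287/154 child,
#' 1867/440 adult; planted enrichment 3. The genome is a 22 x 10 Mb
#' scaled stand-in giving an extended-track coverage fraction near 0.05.
#'
#' @param nChroms,chromLength genome shape (equal-length chromosomes).
#' @param nGenes number of gene regions.
#' @param geneLengthMedian,geneLengthSdlog log-normal gene length law
#'   (median bp, dispersion on the log scale).
#' @param flank extension applied to each gene on both sides, bp.
#' @param nProbes total array probes.
#' @param nSig named list, age group -> c(hyper =, hypo =) significant
#'   probe counts.
#' @param targetEnrichment planted enrichment factor rho >= 0.
#' @param alpha family-wise error rate defining the significance cutoff
#'   alpha / nProbes; significant P-values are uniform on (0, cutoff),
#'   non-significant uniform on (cutoff, 1).
#' @param slopeMeanlog,slopeSdlog log-normal law for |slope| of
#'   significant probes (methylation change per year).
#' @param nullSlopeSd SD of the centered normal slope noise for
#'   non-significant group entries.
#' @return A validated \code{SyntheticConfig} (a classed list).
#' @export
syntheticConfig <- function(nChroms = 22L,
                            chromLength = 1e7,
                            nGenes = 1792L,
                            geneLengthMedian = 2000,
                            geneLengthSdlog = 0.5,
                            flank = 2000L,
                            nProbes = 27578L,
                            nSig = list(fetal = c(hyper = 20L, hypo = 83L),
                                        child = c(hyper = 287L, hypo = 154L),
                                        adult = c(hyper = 1867L, hypo = 440L)),
                            targetEnrichment = 3,
                            alpha = 0.05,
                            slopeMeanlog = log(0.005),
                            slopeSdlog = 0.5,
                            nullSlopeSd = 0.002) {
  if (nChroms < 1L || chromLength < 1)
    stop("genome must have at least one chromosome of positive length")
  if (nGenes < 0L || nProbes < 1L || flank < 0L || targetEnrichment < 0)
    stop("counts must be non-negative and nProbes >= 1")
  if (is.null(names(nSig)) || any(!nzchar(names(nSig))))
    stop("nSig must be a named list, one entry per age group")
  for (g in names(nSig))
    if (!all(c("hyper", "hypo") %in% names(nSig[[g]])))
      stop(sprintf("nSig[['%s']] needs 'hyper' and 'hypo' counts", g))
  totalSig <- sum(vapply(nSig, sum, 1))
  if (totalSig > nProbes)
    stop("significant probe counts exceed nProbes")
  structure(list(nChroms = as.integer(nChroms),
                 chromLength = chromLength,
                 nGenes = as.integer(nGenes),
                 geneLengthMedian = geneLengthMedian,
                 geneLengthSdlog = geneLengthSdlog,
                 flank = as.integer(flank),
                 nProbes = as.integer(nProbes),
                 nSig = nSig,
                 targetEnrichment = targetEnrichment,
                 alpha = alpha,
                 slopeMeanlog = slopeMeanlog,
                 slopeSdlog = slopeSdlog,
                 nullSlopeSd = nullSlopeSd),
            class = "SyntheticConfig")
}

#' Generate the synthetic genome
#'
#' @param config a [syntheticConfig()].
#' @return A \link[GenomeInfoDb]{Seqinfo} with \code{nChroms} chromosomes
#'   \code{chr1..chrN} of \code{chromLength} bp each.
#' @export
generateGenome <- function(config) {
  genomeAssembly(setNames(rep(config$chromLength, config$nChroms),
                          paste0("chr", seq_len(config$nChroms))),
                 name = "synthetic")
}

#' Generate non-overlapping bivalent-like gene regions
#'
#' Gene lengths are log-normal; genes are assigned to chromosomes in
#' proportion to chromosome length and placed uniformly without overlap
#' (before flank extension). Regions may be book-ended; the analysis
#' merges extended regions anyway.
#'
#' @param config a [syntheticConfig()].
#' @param genome the matching [generateGenome()] output.
#' @param seed optional integer seed.
#' @return A \link[GenomicRanges]{GRanges} with a \code{gene_id} column
#'   (unextended coordinates).
#' @export
generateGeneTrack <- function(config, genome, seed = NULL) {
  doGen <- function() {
    n <- config$nGenes
    if (n == 0L)
      return(GRanges(seqinfo = genome))
    lens <- pmax(1, round(rlnorm(n, meanlog = log(config$geneLengthMedian),
                                 sdlog = config$geneLengthSdlog)))
    sl <- seqlengths(genome)
    chrom <- sample(seqlevels(genome), n, replace = TRUE,
                    prob = sl / sum(as.numeric(sl)))
    parts <- split(seq_len(n), factor(chrom, levels = seqlevels(genome)))
    out <- vector("list", length(parts))
    for (i in seq_along(parts)) {
      idx <- parts[[i]]
      if (!length(idx)) next
      L <- sl[[i]]
      li <- lens[idx]
      free <- L - sum(li)
      if (free < 0)
        stop(sprintf("infeasible packing: %d genes (%d bp) on a %d bp chromosome",
                     length(idx), sum(li), L))
      u <- sort(floor(runif(length(idx)) * (free + 1)))
      starts0 <- u + cumsum(c(0, li[-length(li)]))
      out[[i]] <- GRanges(names(parts)[i],
                          IRanges(start = starts0 + 1L, width = li),
                          seqinfo = genome)
    }
    gr <- sort(do.call(c, out[!vapply(out, is.null, TRUE)]))
    mcols(gr)$gene_id <- sprintf("GENE%05d", seq_along(gr))
    gr
  }
  if (is.null(seed)) doGen() else withr::with_seed(seed, doGen())
}

#' Genome coverage fraction of a track
#'
#' @param track a \link[GenomicRanges]{GRanges} (merged or not; merged
#'   internally).
#' @param genome a \link[GenomeInfoDb]{Seqinfo}.
#' @return Covered bp of the merged union divided by total genome bp.
#' @export
trackCoverageFraction <- function(track, genome = seqinfo(track)) {
  trackCoverageBp(mergeTrack(track)) / totalGenomeLength(genome)
}

## Uniform 0-based positions inside the merged track (by covered bp).
.sampleInTrack <- function(n, track) {
  w <- width(track)
  cum <- cumsum(as.numeric(w))
  off <- floor(runif(n) * cum[length(cum)])       # 0 .. C-1
  seg <- findInterval(off, c(0, cum[-length(cum)]))
  list(chrom = as.character(seqnames(track))[seg],
       pos = (start(track)[seg] - 1L) + (off - c(0, cum[-length(cum)])[seg]))
}

## Uniform 0-based positions over the whole genome.
.sampleGenome <- function(n, genome) {
  sl <- as.numeric(seqlengths(genome))
  cum <- cumsum(sl)
  off <- floor(runif(n) * cum[length(cum)])
  chromIdx <- findInterval(off, c(0, cum[-length(cum)]))
  list(chrom = seqlevels(genome)[chromIdx],
       pos = off - c(0, cum[-length(cum)])[chromIdx])
}

## Uniform outside the track: rejection sampling (efficient for small c).
.sampleOutsideTrack <- function(n, track, genome) {
  chrom <- character(n); pos <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- .sampleGenome(length(todo), genome)
    gr <- asPoints(cand$chrom, cand$pos, genome)
    ok <- !overlapsAny(gr, track)
    chrom[todo[ok]] <- cand$chrom[ok]
    pos[todo[ok]] <- cand$pos[ok]
    todo <- todo[!ok]
  }
  list(chrom = chrom, pos = pos)
}

#' Generate a probe-association table with planted enrichment
#'
#' See [syntheticConfig()] for the placement model. Positions are
#' deduplicated (resampled within their placement stratum) so every probe
#' occupies a distinct base pair.
#'
#' @param config a [syntheticConfig()].
#' @param genome the matching genome.
#' @param geneTrack [generateGeneTrack()] output (unextended); the
#'   placement target is its flank-extended merged union.
#' @param seed optional integer seed.
#' @return A probe GRanges in the layout of [readProbeTable()].
#' @export
generateProbeTable <- function(config, genome, geneTrack, seed = NULL) {
  doGen <- function() {
    groups <- names(config$nSig)
    thr <- config$alpha / config$nProbes
    track <- mergeTrack(extendAndClamp(
      GRanges(seqnames(geneTrack), IRanges(start(geneTrack), end(geneTrack)),
              seqinfo = genome), config$flank))
    cFrac <- if (length(track)) trackCoverageFraction(track, genome) else 0
    q <- min(1, config$targetEnrichment * cFrac)
    nHyperTotal <- sum(vapply(config$nSig, `[[`, 1, "hyper"))
    if (length(track) && q * nHyperTotal > trackCoverageBp(track))
      stop("configuration error: planted in-track probes exceed track capacity")

    n <- config$nProbes
    # placement stratum per probe: "track", "outside", or "genome"
    stratum <- rep("genome", n)
    sigGroup <- rep(NA_character_, n)   # group a probe is significant in
    sigDir <- rep(NA_character_, n)
    i <- 0L
    for (g in groups) for (d in c("hyper", "hypo")) {
      cnt <- config$nSig[[g]][[d]]
      if (cnt == 0L) next
      idx <- i + seq_len(cnt)
      sigGroup[idx] <- g
      sigDir[idx] <- d
      if (d == "hyper" && length(track)) {
        inside <- runif(cnt) < q
        stratum[idx][inside] <- "track"
        stratum[idx][!inside] <- "outside"
      }
      i <- i + cnt
    }

    drawPos <- function(strat, m) {
      switch(strat,
             track = .sampleInTrack(m, track),
             outside = .sampleOutsideTrack(m, track, genome),
             genome = .sampleGenome(m, genome))
    }
    chrom <- character(n); pos <- numeric(n)
    for (strat in c("track", "outside", "genome")) {
      sel <- which(stratum == strat)
      if (!length(sel)) next
      s <- drawPos(strat, length(sel))
      chrom[sel] <- s$chrom; pos[sel] <- s$pos
    }
    # dedup within stratum
    for (iter in seq_len(100L)) {
      dup <- which(duplicated(paste(chrom, pos)))
      if (!length(dup)) break
      for (strat in c("track", "outside", "genome")) {
        sel <- dup[stratum[dup] == strat]
        if (!length(sel)) next
        s <- drawPos(strat, length(sel))
        chrom[sel] <- s$chrom; pos[sel] <- s$pos
      }
    }
    if (anyDuplicated(paste(chrom, pos)))
      stop("could not deduplicate probe positions; genome too small")

    ord <- order(match(chrom, seqlevels(genome)), pos)
    gr <- asPoints(chrom[ord], pos[ord], genome)
    mcols(gr)$probe_id <- sprintf("cg%08d", seq_len(n))
    sigGroup <- sigGroup[ord]; sigDir <- sigDir[ord]
    for (g in groups) {
      isSig <- !is.na(sigGroup) & sigGroup == g
      p <- runif(n, thr, 1)
      p[isSig] <- runif(sum(isSig), 0, thr)
      slope <- rnorm(n, 0, config$nullSlopeSd)
      mag <- rlnorm(sum(isSig), config$slopeMeanlog, config$slopeSdlog)
      slope[isSig] <- ifelse(sigDir[isSig] == "hyper", mag, -mag)
      mcols(gr)[[paste0("slope_", g)]] <- slope
      mcols(gr)[[paste0("p_", g)]] <- p
    }
    metadata(gr)$groups <- groups
    gr
  }
  if (is.null(seed)) doGen() else withr::with_seed(seed, doGen())
}

#' Write a complete seeded synthetic study to a directory
#'
#' Emits the three files the analysis consumes: \code{genome.chrom.sizes},
#' \code{genes.bed} (BED4, unextended gene coordinates) and
#' \code{probes.tsv}.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed).
#' @param seed integer seed; the study is fully reproducible from it.
#' @return Invisibly, a named list of the three file paths.
#' @export
generateStudy <- function(config, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generateGenome(config)
  genes <- generateGeneTrack(config, genome, seed = seed)
  probes <- generateProbeTable(config, genome, genes, seed = seed + 1L)
  paths <- list(genome = file.path(dir, "genome.chrom.sizes"),
                genes = file.path(dir, "genes.bed"),
                probes = file.path(dir, "probes.tsv"))
  writeGenome(genome, paths$genome)
  genesOut <- genes
  mcols(genesOut)$name <- genes$gene_id
  mcols(genesOut)$gene_id <- NULL
  writeBed(genesOut, paths$genes)
  writeProbeTable(probes, paths$probes)
  invisible(paths)
}
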