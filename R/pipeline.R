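#' Configuration for a full enrichment analysis run
#'
#' Bundles the input paths and tuning parameters for [runAnalysis()].
#'
#' @param probeTable path to the probe-association TSV
#'   (see [readProbeTable()]).
#' @param geneBed path to the gene-region BED (BED4 name column used as
#'   gene id; unextended coordinates).
#' @param genomeFile path to the chrom.sizes genome file.
#' @param outputDir directory for report files (created if needed).
#' @param alpha family-wise error rate for the Bonferroni cutoff.
#' @param flank gene extension in bp (analysis convention: 2,000).
#' @param kTop top-k size (convention: 100).
#' @param nMc,nPerm Monte Carlo draws for the global and case-control
#'   tests (convention: 50,000 each; reduce for exploration).
#' @param seed integer master seed; per-row seeds are derived from it.
#' @param groups age groups to analyze; default: all groups present in
#'   the probe table.
#' @return A validated \code{AnalysisConfig} (a classed list).
#' @export
analysisConfig <- function(probeTable, geneBed, genomeFile, outputDir,
                           alpha = 0.05, flank = 2000L, kTop = 100L,
                           nMc = 50000L, nPerm = 50000L, seed = 1L,
                           groups = NULL) {
  for (p in c(probeTable, geneBed, genomeFile))
    if (!file.exists(p)) stop("input file not found: ", p)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (flank < 0 || kTop < 1 || nMc < 1 || nPerm < 1)
    stop("flank must be >= 0 and kTop, nMc, nPerm >= 1")
  structure(list(probeTable = probeTable, geneBed = geneBed,
                 genomeFile = genomeFile, outputDir = outputDir,
                 alpha = alpha, flank = as.integer(flank),
                 kTop = as.integer(kTop), nMc = as.integer(nMc),
                 nPerm = as.integer(nPerm), seed = as.integer(seed),
                 groups = groups),
            class = "AnalysisConfig")
}

.stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE))
}

.writeReport <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- format(signif(out[[col]], 4), scientific = FALSE,
                           trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full enrichment analysis end to end
#'
#' Loads the genome, gene regions and probe table; extends the gene
#' regions by the flank and merges them into the bivalent track;
#' partitions each age group's probes ([sitePartition()]); runs the
#' global Monte Carlo enrichment test ([mcEnrichmentTest()]) on every
#' subset (all-significant and unique per group, plus unique-hyper,
#' unique-hypo, top-k-hyper and top-k-hypo where non-empty); runs the
#' hyper-vs-hypo label-permutation comparison ([labelPermutationTest()])
#' for each group with both directions non-empty; and writes the
#' inside/outside gene lists for each group's unique hyper sites.
#'
#' Outputs in \code{outputDir}: \code{global_enrichment.tsv},
#' \code{case_control.tsv}, \code{<group>_hyper_inside_genes.txt} /
#' \code{..._outside_genes.txt}, and \code{manifest.txt} (seed,
#' parameters, input checksums, zero-slope counts). Reports use 4
#' significant figures; a re-run with the same inputs and seed is
#' byte-identical.
#'
#' @param config an [analysisConfig()].
#' @return Invisibly, a list with the unformatted \code{global} and
#'   \code{caseControl} data.frames, the \code{partitions} (named list of
#'   [SitePartition-class]), the merged \code{track}, and output
#'   \code{paths}.
#' @export
runAnalysis <- function(config) {
  stopifnot(inherits(config, "AnalysisConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)

  genome <- .stage("genome", readGenome(config$genomeFile))
  genes <- .stage("genes", {
    g <- readBed(config$geneBed, genome)
    mcols(g)$gene_id <- if (!is.null(mcols(g)$name)) mcols(g)$name
                        else sprintf("GENE%05d", seq_along(g))
    g
  })
  probes <- .stage("probes", readProbeTable(config$probeTable, genome))
  groups <- if (is.null(config$groups)) probeGroups(probes) else config$groups

  extended <- extendAndClamp(genes, config$flank)  # per-gene, for annotation
  track <- mergeTrack(extended)                    # union, for statistics
  threshold <- bonferroniThreshold(length(probes), config$alpha)

  partitions <- .stage("partition", {
    ps <- lapply(groups, function(g)
      sitePartition(probes, g, threshold = threshold, k = config$kTop))
    names(ps) <- groups
    ps
  })

  rowSeed <- local({ i <- 0L; function() { i <<- i + 1L; config$seed + i } })

  globalRows <- list()
  addGlobal <- function(pts, label) {
    if (length(pts) == 0L) return(invisible())
    res <- mcEnrichmentTest(pts, track, genome, nMc = config$nMc,
                            seed = rowSeed(), trackName = label)
    globalRows[[length(globalRows) + 1L]] <<- asReportRow(res)
  }
  .stage("global-enrichment", {
    for (g in groups) {
      p <- partitions[[g]]
      addGlobal(p@significant, paste0("all_", g))
      addGlobal(p@unique, paste0("unique_", g))
    }
    for (g in groups) {
      p <- partitions[[g]]
      addGlobal(p@hyper, paste0("unique_hyper_", g))
      addGlobal(p@hypo, paste0("unique_hypo_", g))
      addGlobal(p@topKHyper, paste0("top", config$kTop, "_hyper_", g))
      addGlobal(p@topKHypo, paste0("top", config$kTop, "_hypo_", g))
    }
  })
  globalTab <- do.call(rbind, globalRows)

  ccRows <- list()
  .stage("case-control", {
    for (g in groups) {
      p <- partitions[[g]]
      if (length(p@hyper) && length(p@hypo))
        ccRows[[length(ccRows) + 1L]] <- asReportRow(labelPermutationTest(
          p@hyper, p@hypo, track, nPerm = config$nPerm, seed = rowSeed(),
          caseName = paste0("unique_hyper_", g),
          controlName = paste0("unique_hypo_", g)))
      if (length(p@topKHyper) && length(p@topKHypo))
        ccRows[[length(ccRows) + 1L]] <- asReportRow(labelPermutationTest(
          p@topKHyper, p@topKHypo, track, nPerm = config$nPerm,
          seed = rowSeed(),
          caseName = paste0("top", config$kTop, "_hyper_", g),
          controlName = paste0("top", config$kTop, "_hypo_", g)))
    }
  })
  ccTab <- if (length(ccRows)) do.call(rbind, ccRows) else NULL

  geneListCounts <- list()
  .stage("gene-lists", {
    for (g in groups) {
      hyper <- partitions[[g]]@hyper
      if (!length(hyper)) next
      split <- partitionByOverlap(hyper, track)
      insideGenes <- nonRedundantGenes(split$inside, extended)
      outsideGenes <- nonRedundantGenes(split$outside, extended)
      writeGeneList(insideGenes,
                    file.path(config$outputDir,
                              paste0(g, "_hyper_inside_genes.txt")))
      writeGeneList(outsideGenes,
                    file.path(config$outputDir,
                              paste0(g, "_hyper_outside_genes.txt")))
      geneListCounts[[g]] <- c(inside_sites = length(split$inside),
                                inside_genes = length(insideGenes),
                                outside_sites = length(split$outside),
                                outside_genes = length(outsideGenes))
    }
  })

  paths <- list(global = file.path(config$outputDir, "global_enrichment.tsv"),
                caseControl = file.path(config$outputDir, "case_control.tsv"),
                manifest = file.path(config$outputDir, "manifest.txt"))
  .writeReport(globalTab, paths$global)
  if (!is.null(ccTab)) .writeReport(ccTab, paths$caseControl)

  manifest <- c(
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("bivalentEnrich"))),
    sprintf("seed\t%d", config$seed),
    sprintf("alpha\t%g", config$alpha),
    sprintf("threshold\t%.6g", threshold),
    sprintf("flank\t%d", config$flank),
    sprintf("k_top\t%d", config$kTop),
    sprintf("n_mc\t%d", config$nMc),
    sprintf("n_perm\t%d", config$nPerm),
    sprintf("n_probes\t%d", length(probes)),
    sprintf("n_gene_regions\t%d", length(genes)),
    sprintf("track_coverage_bp\t%.0f", trackCoverageBp(track)),
    sprintf("md5_%s\t%s", c("probes", "genes", "genome"),
            tools::md5sum(c(config$probeTable, config$geneBed,
                            config$genomeFile))),
    vapply(groups, function(g)
      sprintf("zero_slope_%s\t%d", g, partitions[[g]]@nZeroSlope), ""),
    unlist(lapply(names(geneListCounts), function(g)
      sprintf("%s_%s\t%d", g, names(geneListCounts[[g]]),
              geneListCounts[[g]]))))
  writeLines(manifest, paths$manifest)

  invisible(list(global = globalTab, caseControl = ccTab,
                 partitions = partitions, track = track, paths = paths))
}
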