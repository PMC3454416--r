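#' Bonferroni-corrected significance cutoff
#'
#' Family-wise error control: the per-test cutoff is \code{alpha / nTests}.
#' For the 27,578 probes of a 27k-style methylation array at alpha = 0.05
#' this gives 1.81304e-06.
#'
#' @param nTests number of tests (>= 1).
#' @param alpha family-wise error rate in (0, 1).
#' @return The per-test P-value cutoff.
#' @examples
#' bonferroniThreshold(27578)        # 1.81304e-06
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  if (length(nTests) != 1L || is.na(nTests) || nTests < 1 ||
      nTests != floor(nTests))
    stop("nTests must be a single integer >= 1")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  alpha / nTests
}

#' Read / write a probe-association table
#'
#' Tab-separated with a header line: \code{probe_id}, \code{chrom},
#' \code{position} (0-based point, the first base of the probe), then one
#' \code{slope_<group>} / \code{p_<group>} column pair per age group (the
#' per-group methylation-vs-age regression slope and its P-value).
#' Missing values are not modeled and are rejected.
#'
#' @param path file path.
#' @param genome a \link[GenomeInfoDb]{Seqinfo}; probes on chromosomes
#'   absent from it, or beyond a chromosome bound, are an error (silent
#'   loss would corrupt the enrichment-ratio denominators).
#' @return A width-1 \link[GenomicRanges]{GRanges}, one range per probe,
#'   with metadata columns \code{probe_id} and the slope/p pairs; the age
#'   group labels are in \code{metadata(x)$groups}.
#' @export
readProbeTable <- function(path, genome) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "chrom", "position")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column '%s'", path, miss[1]))
  slopeCols <- grep("^slope_", names(df), value = TRUE)
  groups <- sub("^slope_", "", slopeCols)
  if (!length(groups))
    stop(sprintf("%s: no slope_<group> columns found", path))
  pCols <- paste0("p_", groups)
  miss <- setdiff(pCols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column '%s'", path, miss[1]))
  dup <- which(duplicated(df$probe_id))
  if (length(dup))
    stop(sprintf("%s: line %d: duplicate probe_id '%s'",
                 path, dup[1] + 1L, df$probe_id[dup[1]]))
  numCol <- function(col, check = NULL) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) | if (!is.null(check)) !check(x) else FALSE)
    if (length(bad))
      stop(sprintf("%s: line %d: invalid value '%s' in column '%s'",
                   path, bad[1] + 1L, df[[col]][bad[1]], col))
    x
  }
  pos <- numCol("position", function(x) x >= 0 & x == floor(x))
  missingChrom <- setdiff(unique(df$chrom), seqlevels(genome))
  if (length(missingChrom))
    stop(sprintf("%s: chromosome '%s' not in genome definition",
                 path, missingChrom[1]))
  gr <- asPoints(df$chrom, as.integer(pos), genome)
  mcols(gr)$probe_id <- df$probe_id
  for (g in groups) {
    mcols(gr)[[paste0("slope_", g)]] <- numCol(paste0("slope_", g))
    mcols(gr)[[paste0("p_", g)]] <-
      numCol(paste0("p_", g), function(x) x >= 0 & x <= 1)
  }
  metadata(gr)$groups <- groups
  gr
}

#' @rdname readProbeTable
#' @param probes a probe GRanges as returned by \code{readProbeTable}.
#' @export
writeProbeTable <- function(probes, path) {
  groups <- probeGroups(probes)
  df <- data.frame(probe_id = probes$probe_id,
                   chrom = as.character(seqnames(probes)),
                   position = start(probes) - 1L,
                   check.names = FALSE)
  # %.17g so doubles survive the text round trip exactly
  for (g in groups) {
    df[[paste0("slope_", g)]] <- sprintf("%.17g",
                                         mcols(probes)[[paste0("slope_", g)]])
    df[[paste0("p_", g)]] <- sprintf("%.17g", mcols(probes)[[paste0("p_", g)]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readProbeTable
#' @export
probeGroups <- function(probes) {
  g <- metadata(probes)$groups
  if (is.null(g))
    g <- sub("^slope_", "", grep("^slope_", names(mcols(probes)),
                                 value = TRUE))
  g
}

.groupCols <- function(probes, group) {
  pc <- paste0("p_", group)
  sc <- paste0("slope_", group)
  if (!all(c(pc, sc) %in% names(mcols(probes))))
    stop(sprintf("age group '%s' not present in probe table", group))
  list(p = mcols(probes)[[pc]], slope = mcols(probes)[[sc]])
}

#' Probe subsets by significance, uniqueness, direction and rank
#'
#' \code{significantSites} returns the probes with association P strictly
#' below the cutoff in the given age group. \code{uniqueSites} keeps those
#' that are additionally \emph{not} significant (P >= cutoff) in every
#' other group. \code{splitHyperHypo} divides a subset by the sign of the
#' group's slope: hyper-methylated = slope > 0 (methylation increases with
#' age), hypo = slope < 0; slope exactly 0 is assigned to neither.
#' \code{topKSites} takes the k most significant probes of a subset, with
#' the deterministic tie-break P ascending, |slope| descending, probe_id
#' ascending.
#'
#' All take and return width-1 probe GRanges carrying the probe metadata
#' columns, so subsets compose.
#'
#' @param probes probe GRanges from [readProbeTable()].
#' @param group age group label.
#' @param threshold significance cutoff (see [bonferroniThreshold()]).
#' @return A probe GRanges subset; \code{splitHyperHypo} returns
#'   \code{list(hyper =, hypo =, zero =)}.
#' @export
significantSites <- function(probes, group, threshold) {
  st <- .groupCols(probes, group)
  probes[st$p < threshold]
}

#' @rdname significantSites
#' @export
uniqueSites <- function(probes, group, threshold) {
  groups <- probeGroups(probes)
  st <- .groupCols(probes, group)
  keep <- st$p < threshold
  for (g in setdiff(groups, group))
    keep <- keep & .groupCols(probes, g)$p >= threshold
  probes[keep]
}

#' @rdname significantSites
#' @param sites a subset of \code{probes} (matched back by \code{probe_id}).
#' @export
splitHyperHypo <- function(probes, sites, group) {
  idx <- match(sites$probe_id, probes$probe_id)
  if (anyNA(idx))
    stop("sites contain probe_ids absent from the probe table")
  slope <- .groupCols(probes, group)$slope[idx]
  list(hyper = sites[slope > 0],
       hypo = sites[slope < 0],
       zero = sites[slope == 0])
}

#' @rdname significantSites
#' @param k number of sites to keep.
#' @export
topKSites <- function(probes, sites, group, k = 100L) {
  if (k < 1L) stop("k must be >= 1")
  idx <- match(sites$probe_id, probes$probe_id)
  if (anyNA(idx))
    stop("sites contain probe_ids absent from the probe table")
  st <- .groupCols(probes, group)
  ord <- order(st$p[idx], -abs(st$slope[idx]), sites$probe_id)
  sites[ord[seq_len(min(k, length(sites)))]]
}

#' Partition one age group's probes into every analyzed subset
#'
#' Applies [significantSites()], [uniqueSites()], [splitHyperHypo()] and
#' [topKSites()] in one pass and returns a validated
#' [SitePartition-class]. The significance cutoff defaults to the
#' Bonferroni correction computed from the number of probes in the table.
#'
#' @inheritParams significantSites
#' @param threshold cutoff; default \code{bonferroniThreshold(length(probes),
#'   alpha)}.
#' @param alpha family-wise error rate used for the default threshold.
#' @param k top-k size (the analysis convention is 100).
#' @return A [SitePartition-class].
#' @export
sitePartition <- function(probes, group,
                          threshold = bonferroniThreshold(length(probes), alpha),
                          alpha = 0.05, k = 100L) {
  sig <- significantSites(probes, group, threshold)
  uni <- uniqueSites(probes, group, threshold)
  dir <- splitHyperHypo(probes, uni, group)
  new("SitePartition",
      group = group,
      significant = sig,
      unique = uni,
      hyper = dir$hyper,
      hypo = dir$hypo,
      topKHyper = if (length(dir$hyper)) topKSites(probes, dir$hyper, group, k)
                  else dir$hyper,
      topKHypo = if (length(dir$hypo)) topKSites(probes, dir$hypo, group, k)
                 else dir$hypo,
      threshold = threshold,
      k = as.integer(k),
      nZeroSlope = length(dir$zero))
}
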