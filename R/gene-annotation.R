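#' Map probe points to the gene regions containing them
#'
#' Annotation uses the per-gene (unmerged) extended intervals so a point
#' inside two overlapping extended genes is recorded against both; the
#' merged union is only for coverage and overlap statistics. Points
#' hitting no gene map to an empty set.
#'
#' @param points width-1 \link[GenomicRanges]{GRanges}.
#' @param genes \link[GenomicRanges]{GRanges} with a \code{gene_id}
#'   metadata column (extended, unmerged).
#' @return A \link[IRanges]{CharacterList} parallel to \code{points}: the
#'   gene ids containing each point.
#' @examples
#' genome <- genomeAssembly(c(c1 = 10000L))
#' genes <- asTrack("c1", c(100, 150), c(300, 400), genome)
#' genes$gene_id <- c("A", "B")
#' annotatePoints(asPoints("c1", c(200L, 350L, 900L), genome), genes)
#' @export
annotatePoints <- function(points, genes) {
  if (is.null(genes$gene_id))
    stop("genes must carry a gene_id metadata column")
  hits <- findOverlaps(points, genes)
  S4Vectors::splitAsList(genes$gene_id[subjectHits(hits)],
                         factor(queryHits(hits), levels = seq_along(points)))
}

#' @rdname annotatePoints
#' @return \code{nonRedundantGenes}: sorted unique gene ids hit by any
#'   point (the deduplicated gene list fed to ontology tools).
#' @export
nonRedundantGenes <- function(points, genes) {
  sort(unique(unlist(annotatePoints(points, genes), use.names = FALSE)))
}

#' Split points by overlap with a track
#'
#' Disjoint, exhaustive split of a point set into the points inside and
#' outside the merged track union.
#'
#' @param points width-1 \link[GenomicRanges]{GRanges}.
#' @param track merged \link[GenomicRanges]{GRanges}.
#' @return \code{list(inside =, outside =)}, both GRanges subsets of
#'   \code{points}; \code{length(inside) + length(outside) ==
#'   length(points)}.
#' @export
partitionByOverlap <- function(points, track) {
  .assertMerged(track)
  hit <- overlapsAny(points, track)
  list(inside = points[hit], outside = points[!hit])
}

#' Write a plain one-id-per-line gene list
#'
#' The format ontology web tools ingest.
#'
#' @param ids character vector of gene ids.
#' @param path file path.
#' @export
writeGeneList <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
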