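#' Read and write BED3/BED4 tracks
#'
#' Tab-separated, 0-based, half-open. An optional 4th column is carried as
#' the region name (metadata column \code{name}); lines may mix 3 and 4
#' fields. The round trip \code{writeBed(readBed(x))} is lossless for
#' chrom/start/end/name.
#'
#' @param path file path.
#' @param genome optional \link[GenomeInfoDb]{Seqinfo}; when supplied,
#'   intervals are bounds-checked against it and the returned GRanges
#'   carries it. Otherwise seqlengths are left unset.
#' @return \code{readBed}: a \link[GenomicRanges]{GRanges}, unmerged, with
#'   a \code{name} column when any line had one.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tGENE1", p)
#' readBed(p)
#' @export
readBed <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") &
    !startsWith(lines, "browser") & !startsWith(lines, "#")
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(sprintf("%s: line %d: expected at least 3 tab-separated fields",
                 path, lineno[bad[1]]))
  chrom <- vapply(parts, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
  if (length(bad))
    stop(sprintf("%s: line %d: start/end must be integers",
                 path, lineno[bad[1]]))
  bad <- which(s < 0 | e <= s)
  if (length(bad))
    stop(sprintf("%s: line %d: need 0 <= start < end (got %d, %d)",
                 path, lineno[bad[1]], as.integer(s[bad[1]]),
                 as.integer(e[bad[1]])))
  gr <- GRanges(chrom, IRanges(as.integer(s) + 1L, as.integer(e)))
  if (any(nf >= 4L))
    mcols(gr)$name <- ifelse(nf >= 4L, vapply(parts, function(p)
      if (length(p) >= 4L) p[[4L]] else NA_character_, ""), NA_character_)
  if (!is.null(genome)) {
    missing <- setdiff(unique(chrom), seqlevels(genome))
    if (length(missing))
      stop(sprintf("%s: chromosome '%s' not in genome definition",
                   path, missing[1]))
    seqinfo(gr) <- genome
    .checkBounds(gr)
  }
  gr
}

#' @rdname readBed
#' @param track a \link[GenomicRanges]{GRanges}; written as BED4 when a
#'   \code{name} metadata column is present, BED3 otherwise.
#' @export
writeBed <- function(track, path) {
  chrom <- as.character(seqnames(track))
  s <- format(start(track) - 1L, scientific = FALSE, trim = TRUE)
  e <- format(end(track), scientific = FALSE, trim = TRUE)
  nm <- mcols(track)$name
  lines <- if (!is.null(nm)) paste(chrom, s, e, nm, sep = "\t")
           else paste(chrom, s, e, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
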