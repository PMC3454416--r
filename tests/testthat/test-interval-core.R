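test_that("mergeTrack collapses overlapping, adjacent and cross-chromosome cases", {
  genome <- toyGenome(c(c1 = 1000L, c2 = 1000L))
  # overlapping pair
  m <- mergeTrack(asTrack("c1", c(100, 150), c(200, 300), genome))
  expect_equal(start(m) - 1L, 100L)
  expect_equal(end(m), 300L)
  # adjacent in half-open coordinates
  m <- mergeTrack(asTrack("c1", c(100, 200), c(200, 300), genome))
  expect_length(m, 1L)
  expect_equal(end(m) - (start(m) - 1L), 200L)
  # different chromosomes stay apart
  m <- mergeTrack(asTrack(c("c1", "c2"), c(100, 100), c(200, 200), genome))
  expect_length(m, 2L)
  # idempotence and coverage never increasing
  raw <- asTrack("c1", c(10, 15, 500), c(100, 120, 600), genome)
  m1 <- mergeTrack(raw)
  expect_identical(m1, mergeTrack(m1))
  expect_lte(trackCoverageBp(m1), sum(width(raw)))
  expect_true(isMergedTrack(m1))
  expect_false(isMergedTrack(raw))
})

test_that("interval construction rejects out-of-bounds coordinates", {
  genome <- toyGenome(c(c1 = 1000L))
  expect_error(asTrack("c1", 900, 1100, genome), "bounds")
  expect_error(asTrack("c9", 0, 10, genome), "bounds|c9")
  expect_error(asPoints("c1", 1000L, genome), "bounds")
})

test_that("extendAndClamp grows by the flank and clamps at both ends", {
  genome <- toyGenome(c(c1 = 10000L))
  ext <- extendAndClamp(asTrack("c1", 1000, 2000, genome), 2000)
  expect_equal(start(ext) - 1L, 0L)       # clamp at 0
  expect_equal(end(ext), 4000L)
  ext <- extendAndClamp(asTrack("c1", 9000, 9500, genome), 2000)
  expect_equal(start(ext) - 1L, 7000L)
  expect_equal(end(ext), 10000L)          # clamp at chromosome length
  tr <- asTrack("c1", 500, 600, genome)
  expect_identical(granges(extendAndClamp(tr, 0)), granges(tr))
  expect_error(extendAndClamp(tr, -1), "flank")
})

test_that("pointsInTrack honors half-open boundaries", {
  genome <- toyGenome(c(c1 = 1000L))
  track <- mergeTrack(asTrack("c1", 100, 200, genome))
  expect_equal(pointsInTrack(asPoints("c1", c(150L, 500L), genome), track), 1L)
  expect_equal(pointsInTrack(asPoints("c1", 200L, genome), track), 0L)
  expect_equal(pointsInTrack(asPoints("c1", 100L, genome), track), 1L)
  unmerged <- asTrack("c1", c(100, 150), c(200, 250), genome)
  expect_error(pointsInTrack(asPoints("c1", 150L, genome), unmerged), "merged")
})

test_that("pointsInTrack agrees with a brute-force scan on random instances", {
  genome <- toyGenome(c(c1 = 2000L, c2 = 1500L))
  withr::with_seed(42, {
    for (i in 1:100) {
      track <- randomMergedTrack(genome, sample.int(20, 1), maxLen = 80L)
      pts <- randomPoints(genome, sample.int(50, 1))
      expect_identical(pointsInTrack(pts, track), bruteForceCount(pts, track))
    }
  })
})

test_that("trackCoverageBp sums covered base pairs", {
  genome <- toyGenome(c(c1 = 1000L, c2 = 1000L))
  expect_equal(trackCoverageBp(mergeTrack(asTrack("c1", 100, 200, genome))), 100)
  expect_equal(trackCoverageBp(GRanges(seqinfo = genome)), 0)
  expect_equal(trackCoverageBp(
    mergeTrack(asTrack(c("c1", "c2"), c(0, 0), c(10, 10), genome))), 20)
})

test_that("enrichmentRatio matches hand-evaluated cases and sentinels", {
  genome <- toyGenome(c(c1 = 1000L))
  track <- mergeTrack(asTrack("c1", 100, 200, genome))
  expect_equal(enrichmentRatio(asPoints("c1", c(150L, 500L, 700L), genome),
                               track, genome), (1/3) / (99/997))
  expect_equal(enrichmentRatio(asPoints("c1", c(110L, 120L, 130L), genome),
                               track, genome), 1 / (97/997))
  expect_equal(enrichmentRatio(asPoints("c1", c(500L, 700L), genome),
                               track, genome), 0)
  # track is exactly the probe base pair: C - k = 0 with k > 0
  bp <- mergeTrack(asTrack("c1", 150, 151, genome))
  expect_identical(enrichmentRatio(asPoints("c1", 150L, genome), bp, genome),
                   Inf)
})

test_that("enrichmentRatio is 1 in expectation for track-independent points", {
  genome <- toyGenome(c(c1 = 100000L))
  track <- mergeTrack(asTrack("c1", seq(0, 90000, by = 10000),
                              seq(1000, 91000, by = 10000), genome))  # c = 0.1
  withr::with_seed(7, {
    ratios <- replicate(200, enrichmentRatio(randomPoints(genome, 100L),
                                             track, genome))
  })
  # CLT bound: sd(ratio) ~ sd(Bin(100, .1))/10 = 0.3, so 4 SE ~ 0.085
  expect_lt(abs(mean(ratios) - 1), 4 * sd(ratios) / sqrt(length(ratios)))
})

test_that("randomizeTrack preserves multisets, stays in bounds, is seeded", {
  genome <- toyGenome(c(c1 = 1000L, c2 = 500L))
  track <- mergeTrack(asTrack(c("c1", "c1", "c2"), c(100, 300, 50),
                              c(110, 320, 80), genome))
  r1 <- randomizeTrack(track, seed = 5L)
  r2 <- randomizeTrack(track, seed = 5L)
  expect_identical(r1, r2)                       # determinism contract
  expect_true(isMergedTrack(r1))
  expect_identical(lengthMultiset(r1), lengthMultiset(track))
  expect_identical(gapMultiset(r1), gapMultiset(track))
  # single segment: only the length is preserved, start within bounds
  single <- mergeTrack(asTrack("c1", 400, 500, genome))
  withr::with_seed(9, for (i in 1:25) {
    r <- randomizeTrack(single)
    expect_equal(width(r), 100L)
    expect_gte(start(r) - 1L, 0L)
    expect_lte(end(r), 1000L)
  })
  # segments + gaps exactly filling the chromosome leave a single layout
  tight <- toyGenome(c(c1 = 105L))
  cramped <- mergeTrack(asTrack("c1", c(0, 55), c(50, 105), tight))
  r <- randomizeTrack(cramped, seed = 1L)
  expect_identical(granges(r), granges(cramped))  # slack 0: layout forced
})

test_that("BED round trip is lossless and parse errors carry line numbers", {
  genome <- toyGenome(c(chr1 = 100000L))
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tGENE1", "chr1\t500\t800\tGENE2"), p)
  gr <- readBed(p, genome)
  expect_equal(start(gr) - 1L, c(100L, 500L))
  expect_equal(end(gr), c(200L, 800L))
  expect_equal(gr$name, c("GENE1", "GENE2"))
  p2 <- withr::local_tempfile(fileext = ".bed")
  writeBed(gr, p2)
  expect_identical(readLines(p2), readLines(p))   # write(read(x)) == x
  # malformed lines
  writeLines(c("chr1\t100\t200", "chr1\t300\t250"), p)
  expect_error(readBed(p), "line 2")
  writeLines("chr1\t100", p)
  expect_error(readBed(p), "line 1")
  writeLines("chr1\tx\t200", p)
  expect_error(readBed(p), "line 1")
  # unknown chromosome against a genome
  writeLines("chrZ\t10\t20", p)
  expect_error(readBed(p, genome), "chrZ")
})

test_that("chrom.sizes genome files round trip and validate", {
  p <- withr::local_tempfile(fileext = ".sizes")
  writeLines(c("chr1\t1000", "chr2\t500"), p)
  g <- readGenome(p)
  expect_equal(totalGenomeLength(g), 1500)
  p2 <- withr::local_tempfile(fileext = ".sizes")
  writeGenome(g, p2)
  expect_identical(readLines(p2), readLines(p))
  writeLines(c("chr1\t1000", "chr2\t-5"), p)
  expect_error(readGenome(p), "line 2")
})
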