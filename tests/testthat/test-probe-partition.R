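test_that("bonferroniThreshold reproduces the 27k-array cutoff and validates", {
  expect_equal(signif(bonferroniThreshold(27578, 0.05), 6), 1.81304e-06)
  expect_equal(bonferroniThreshold(10, 0.05), 0.005)
  expect_equal(bonferroniThreshold(1, 0.05), 0.05)
  expect_error(bonferroniThreshold(0, 0.05), "nTests")
  expect_error(bonferroniThreshold(10, 1), "alpha")
  expect_error(bonferroniThreshold(10, 0), "alpha")
})

# three-group probe set exercising significance, uniqueness and direction
threeGroupProbes <- function() {
  genome <- toyGenome(c(c1 = 10000L))
  thr <- 1e-4
  probeSet(genome, "c1", c(10L, 20L, 30L, 40L, 50L, 60L),
           probe_id = paste0("cg", 1:6),
           # cg1: adult+child sig; cg2: adult only; cg3: all three;
           # cg4: child only; cg5: none; cg6: exactly at threshold in adult
           slope_adult = c(0.3, -0.2, 0.1, 0.2, 0.1, 0.4),
           p_adult = c(1e-8, 1e-8, 1e-9, 0.5, 0.2, thr),
           slope_child = c(0.1, 0.2, -0.3, 0, 0.1, 0.1),
           p_child = c(1e-7, 0.5, 1e-8, 1e-6, 0.9, 0.5),
           slope_fetal = c(0.1, 0.1, 0.2, 0.3, 0.1, 0.1),
           p_fetal = c(0.5, 0.5, 1e-7, 0.5, 0.5, 0.5))
}

test_that("significantSites uses strict inequality", {
  probes <- threeGroupProbes()
  sig <- significantSites(probes, "adult", 1e-4)
  expect_setequal(sig$probe_id, c("cg1", "cg2", "cg3"))  # cg6 at p == thr: out
  expect_length(significantSites(probes[0], "adult", 1e-4), 0L)
  expect_error(significantSites(probes, "elderly", 1e-4), "elderly")
  # p = 0 is included
  p0 <- probes
  mcols(p0)$p_adult[5] <- 0
  expect_true("cg5" %in% significantSites(p0, "adult", 1e-4)$probe_id)
})

test_that("uniqueSites requires non-significance in both other groups", {
  probes <- threeGroupProbes()
  thr <- 1e-4
  expect_setequal(uniqueSites(probes, "adult", thr)$probe_id, "cg2")
  expect_setequal(uniqueSites(probes, "child", thr)$probe_id, "cg4")
  expect_length(uniqueSites(probes, "fetal", thr), 0L)  # cg3 sig everywhere
  # unique sets are pairwise disjoint and within significant
  for (g in c("adult", "child", "fetal")) {
    u <- uniqueSites(probes, g, thr)$probe_id
    expect_true(all(u %in% significantSites(probes, g, thr)$probe_id))
    for (h in setdiff(c("adult", "child", "fetal"), g))
      expect_length(intersect(u, uniqueSites(probes, h, thr)$probe_id), 0L)
  }
})

test_that("splitHyperHypo assigns by slope sign; zero goes to neither", {
  genome <- toyGenome(c(c1 = 1000L))
  probes <- probeSet(genome, "c1", c(1L, 2L, 3L),
                     probe_id = c("a", "b", "c"),
                     slope_adult = c(0.3, -0.2, 0),
                     p_adult = c(1e-8, 1e-8, 1e-8))
  s <- splitHyperHypo(probes, probes, "adult")
  expect_equal(s$hyper$probe_id, "a")
  expect_equal(s$hypo$probe_id, "b")
  expect_equal(s$zero$probe_id, "c")
  expect_length(intersect(s$hyper$probe_id, s$hypo$probe_id), 0L)
  bad <- probeSet(genome, "c1", 9L, probe_id = "zz",
                  slope_adult = 1, p_adult = 0.5)
  expect_error(splitHyperHypo(probes, bad, "adult"), "absent")
})

test_that("topKSites ranks by P, then |slope| desc, then probe_id", {
  genome <- toyGenome(c(c1 = 1000L))
  probes <- probeSet(genome, "c1", 1:5,
                     probe_id = c("e", "d", "c", "b", "a"),
                     slope_adult = c(0.1, 0.5, 0.2, 0.2, 0.2),
                     p_adult = c(1e-9, 1e-7, 1e-7, 1e-7, 1e-5))
  top2 <- topKSites(probes, probes, "adult", 2L)
  expect_equal(top2$probe_id, c("e", "d"))  # smallest P, then larger |slope|
  top4 <- topKSites(probes, probes, "adult", 4L)
  expect_equal(top4$probe_id, c("e", "d", "b", "c"))  # tie by probe_id asc
  expect_length(topKSites(probes, probes, "adult", 100L), 5L)
})

test_that("probe tables round trip and reject malformed input", {
  genome <- toyGenome(c(c1 = 100000L))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tchrom\tposition\tslope_adult\tp_adult",
               "cg1\tc1\t100\t0.25\t1e-08",
               "cg2\tc1\t200\t-0.5\t0.9",
               "cg3\tc1\t300\t0.125\t0.5"), p)
  probes <- readProbeTable(p, genome)
  expect_length(probes, 3L)
  expect_equal(probeGroups(probes), "adult")
  expect_equal(start(probes) - 1L, c(100L, 200L, 300L))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeProbeTable(probes, p2)
  probes2 <- readProbeTable(p2, genome)
  expect_identical(mcols(probes)$slope_adult, mcols(probes2)$slope_adult)
  expect_identical(mcols(probes)$p_adult, mcols(probes2)$p_adult)
  expect_identical(granges(probes), granges(probes2))
  # NA p-value: missingness is not modeled
  writeLines(c("probe_id\tchrom\tposition\tslope_adult\tp_adult",
               "cg1\tc1\t100\t0.25\tNA"), p)
  expect_error(readProbeTable(p, genome), "line 2")
  # duplicate probe id
  writeLines(c("probe_id\tchrom\tposition\tslope_adult\tp_adult",
               "cg1\tc1\t100\t0.2\t0.5", "cg1\tc1\t200\t0.2\t0.5"), p)
  expect_error(readProbeTable(p, genome), "duplicate")
  # missing column
  writeLines(c("probe_id\tchrom\tposition\tslope_adult",
               "cg1\tc1\t100\t0.2"), p)
  expect_error(readProbeTable(p, genome), "p_adult")
  # chromosome absent from the genome is an error, not a silent drop
  writeLines(c("probe_id\tchrom\tposition\tslope_adult\tp_adult",
               "cg1\tc9\t100\t0.2\t0.5"), p)
  expect_error(readProbeTable(p, genome), "c9")
})

test_that("sitePartition satisfies the partition algebra on synthetic data", {
  cfg <- syntheticConfig(nChroms = 2L, chromLength = 2e5, nGenes = 30L,
                         nProbes = 600L,
                         nSig = list(fetal = c(hyper = 5L, hypo = 10L),
                                     child = c(hyper = 30L, hypo = 15L),
                                     adult = c(hyper = 80L, hypo = 25L)))
  genome <- generateGenome(cfg)
  genes <- generateGeneTrack(cfg, genome, seed = 3L)
  probes <- generateProbeTable(cfg, genome, genes, seed = 4L)
  parts <- lapply(c("fetal", "child", "adult"), function(g)
    sitePartition(probes, g))
  for (p in parts) {
    expect_s4_class(p, "SitePartition")
    expect_true(all(siteSubset(p, "unique")$probe_id %in%
                    siteSubset(p, "significant")$probe_id))
    expect_equal(length(siteSubset(p, "hyper")) +
                 length(siteSubset(p, "hypo")) + p@nZeroSlope,
                 length(siteSubset(p, "unique")))
  }
  # deterministic stage: same input, same partitions
  parts2 <- sitePartition(probes, "adult")
  expect_identical(siteSubset(parts2, "hyper")$probe_id,
                   siteSubset(parts[[3]], "hyper")$probe_id)
  # generator plants the configured counts (groups independent, so the
  # significant set equals the planted set here)
  expect_equal(length(siteSubset(parts[[3]], "hyper")), 80L)
  expect_equal(length(siteSubset(parts[[2]], "hypo")), 15L)
})
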