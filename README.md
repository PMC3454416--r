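# bivalentEnrich

Do CpG sites whose DNA methylation changes with age fall inside **bivalent
chromatin domains** — gene regions carrying both the activating H3K4me3 and
the repressive H3K27me3 marks — more often than chance would allow?
`bivalentEnrich` implements the complete genome-coordinate analysis behind
that question for promoter-biased methylation arrays (27k-style), aimed at
epigenomics researchers who have a probe-level association table (per-probe
regression slope and P-value against age, per age group) and a BED track of
bivalent gene regions.

## The statistics

**Partitioning.** Probes are filtered at a Bonferroni-corrected cutoff
α/n (for n = 27,578 probes at α = 0.05 this is 1.81304×10⁻⁶), split into
per-age-group significant sets, sets *unique* to one group (significant in
it, non-significant in every other), hyper- (slope > 0) versus
hypo-methylated (slope < 0) subsets, and the top-k most significant sites
per direction.

**Global enrichment.** Each probe is a single genomic point (the first
base of the probe). With n points, k of them inside the merged, ±2 kb
extended gene track of C covered bp on a G bp genome, the enrichment ratio
is

    E = (k / n) / ((C − k) / (G − n)),

the proportion of probe coordinates covered by the track over the
proportion of non-probe coordinates covered. Significance comes from a
Monte Carlo null that holds the probes fixed and randomizes the track,
preserving the per-chromosome multisets of segment lengths and of gaps
between consecutive segments; with the one-sided add-one estimator
P = (1 + #{null ≥ observed}) / (1 + n_MC), 50,000 draws give a P-value
floor of 0.00002.

**Hyper vs hypo.** Two disjoint probe subsets are compared by permuting
the case/control labels over the pooled points (group sizes preserved);
the fold difference is the ratio of the two in-track proportions.

A seeded synthetic-study generator plants a configurable enrichment factor
ρ through the placement probability q = min(1, ρ·c) (c = track coverage
fraction), so the whole pipeline can be validated by parameter recovery
without any external data.

## Worked example

Simulate a small two-group study with a planted enrichment of 4 and run
the full analysis:

```r
library(bivalentEnrich)

cfg <- syntheticConfig(nChroms = 2L, chromLength = 1e6, nGenes = 60L,
                       geneLengthMedian = 1500, nProbes = 2000L,
                       nSig = list(child = c(hyper = 40L, hypo = 30L),
                                   adult = c(hyper = 120L, hypo = 60L)),
                       targetEnrichment = 4)
paths <- generateStudy(cfg, "study", seed = 41L)
config <- analysisConfig(paths$probes, paths$genes, paths$genome,
                         outputDir = "study/results",
                         nMc = 5000L, nPerm = 5000L, seed = 5L, kTop = 20L)
res <- runAnalysis(config)

res$partitions$adult
#> SitePartition for group 'adult' (threshold 2.5e-05)
#>   significant: 180  unique: 180  hyper: 120  hypo: 60  zero-slope: 0
#>   top-20 hyper: 20  top-20 hypo: 20

res$global[res$global$track_name %in%
           c("unique_hyper_adult", "unique_hypo_adult"),
           c("track_name", "n_points", "observed_overlap", "enrichment", "p_value")]
#>            track_name n_points observed_overlap enrichment    p_value
#> 9  unique_hyper_adult      120               75  3.7798170 0.00019996
#> 10  unique_hypo_adult       60                8  0.8062218 0.81643671

res$caseControl[3, c("case_name", "control_name", "fold_difference", "p_value")]
#>            case_name      control_name fold_difference    p_value
#> 3 unique_hyper_adult unique_hypo_adult          4.6875 0.00019996
```

Reading the numbers: of the 120 adult-unique hyper-methylated probes, 75
sit inside the bivalent track — an enrichment ratio of 3.78 whose P-value
(0.0002) is at the floor attainable with 5,000 null draws, i.e. the
observed overlap beat every randomized track. The hypo-methylated probes
show no enrichment (ratio 0.81, P = 0.82), and the label-permutation test
confirms the hyper/hypo contrast (fold difference 4.69, P = 0.0002). The
measured hyper enrichment recovers the planted factor of 4 up to sampling
noise in a single replicate.

`runAnalysis()` also writes `global_enrichment.tsv`, `case_control.tsv`,
per-group inside/outside gene lists, and a `manifest.txt` from which the
run is byte-for-byte reproducible. A command-line front end with
`simulate` / `partition` / `enrich` / `compare` / `run-all` subcommands is
in `inst/scripts/bivalent-pipeline.R`.

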