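---
title: "Testing enrichment of age-associated methylation sites in bivalent chromatin"
author: "bivalentEnrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing enrichment of age-associated methylation sites in bivalent chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalentEnrich)
```

## The question and the model

DNA methylation at individual CpG sites drifts with age, and sites that
*gain* methylation (hyper-methylated, positive methylation-vs-age slope)
have been observed to concentrate in bivalent chromatin domains — gene
regions simultaneously marked by H3K4me3 and H3K27me3, transcriptionally
poised and characteristic of developmental regulators. This package
formalizes that observation as two resampling tests over genome
coordinates.

The data are (i) a probe-association table: one row per array CpG probe
with its genomic point position and, per age group, the regression slope
of methylation on age and its P-value; (ii) a track of bivalent gene
regions; (iii) a chromosome-length table. Probes are treated as single
base-pair points at the first base of the probe; gene regions are
extended by a flank on both sides and merged into a disjoint union so no
base pair is counted twice.

### Global enrichment

With $n$ probe points, $k$ of them inside the merged track, $C$ covered
base pairs and $G$ genome base pairs, the enrichment ratio is

$$E = \frac{k/n}{(C-k)/(G-n)},$$

the proportion of probe coordinates covered by the track divided by the
proportion of *non-probe* coordinates covered. Because each probe
occupies exactly one base pair, in-track probes are subtracted from the
non-probe numerator and all probes from its denominator; for realistic
$C \gg k$ the correction is negligible but it keeps the two proportions
exactly complementary.

Significance comes from a track-randomization Monte Carlo null: probe
coordinates are held fixed and the track is randomized per chromosome,
preserving the multiset of segment lengths and the multiset of gaps
between consecutive segments. The compared statistic is the in-track
point count (not the ratio), one-sided towards enrichment, with the
add-one estimator $P = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{MC})$.
This estimator is valid (never anti-conservative under the null), never
returns zero, and at the conventional $n_{MC} = 50{,}000$ its floor is
$1/50{,}001$, which prints as 0.00002 at five decimals.

The null's assumptions are worth stating: segment lengths and spacings
are what matter about the track's genomic structure, segments never
change chromosome, and the probe background is taken as given. A
one-sided test is the right shape for the scientific question ("more
often than chance?"); depleted subsets simply report large P-values.

### Hyper versus hypo: label permutation

Whether hyper-methylated sites overlap the track more than
hypo-methylated sites is a two-sample question on the *same* track, so
the track is held fixed and the case/control labels are permuted over the
pooled points, preserving group sizes — the standard exchangeability
null. The statistic is the case in-track count (equivalent to the case
proportion at fixed group size); the reported effect size is the fold
difference, the ratio of the two in-track proportions. Note this is not
the ratio of the two sets' global enrichment ratios: the fold difference
compares proportions of points directly and has a different denominator
structure, so the two summaries need not be numerically consistent.

The two point sets must be disjoint; overlapping membership would break
exchangeability and is rejected rather than repaired.

## Coordinate and numerical conventions

* **0-based half-open everywhere on disk** (BED, chrom.sizes, the probe
  table's `position`); in memory, standard 1-based GRanges, converted at
  I/O. A probe at position $p$ is the interval $[p, p+1)$; a point at a
  segment's `end` coordinate is *outside* it.
* **Merging before measuring.** Extended gene regions frequently overlap;
  all coverage and overlap statistics use the merged union, while gene
  annotation deliberately uses the unmerged per-gene intervals so a probe
  inside two overlapping genes is credited to both. Both the raw hit
  count and the deduplicated ("non-redundant") gene count are available,
  since either convention is defensible for downstream ontology lists.
* **Randomization layout.** Per chromosome the alternating
  length/gap layout is rebuilt with both multisets independently,
  uniformly permuted, then shifted by a leading offset drawn uniformly
  over the feasible slack. Only *internal* gaps are preserved — the
  distances between regions — while the flanks to the chromosome ends are
  free; preserving flanks as well would pin the layout entirely on dense
  chromosomes. Whether the original browser-based implementations permute
  gap/length pairings jointly is not documented anywhere we know of;
  independent permutation is this package's fixed, documented choice, and
  the single-segment case reduces to a uniform start position, which is
  tested by goodness of fit.
* **Thresholding.** Significance is strict (`p < cutoff`); "not
  significant elsewhere" is `p >= cutoff`, so the two regimes are
  exhaustive and a probe exactly at the cutoff is non-significant. The
  cutoff is always computed as $\alpha/n$ from the table actually loaded,
  never hard-coded; with the canonical 27,578-probe array it reproduces
  1.81304e-06.
* **Slope exactly zero** belongs to neither direction (both definitions
  are strict inequalities); such sites are counted and reported in the
  run manifest rather than silently assigned.
* **Top-k tie-break:** P ascending, then |slope| descending, then probe
  id ascending — deterministic, and favouring larger effects among equal
  P-values. Top-k sets are taken per direction after the hyper/hypo
  split, which is what makes "top 100 hyper" and "top 100 hypo" sets of
  equal size.
* **Sentinels.** Enrichment is 0 when no point is in the track and +Inf
  when the track consists only of probe base pairs; the fold difference
  is +Inf when only the case set touches the track and NaN when neither
  does.
* **Missing data are errors.** Probes on chromosomes absent from the
  genome definition, or with non-numeric statistics, abort the load:
  silently dropping rows would corrupt both proportions' denominators.
* **Determinism.** Every stochastic function takes a `seed` and scopes it
  (the caller's RNG state is untouched); the pipeline derives one seed
  per report row from a master seed, so a re-run is byte-identical and
  the manifest suffices to reproduce every number.

## The background denominator

The enrichment ratio uses the whole genome as the non-probe background.
27k-style arrays are strongly promoter-biased, and bivalent domains are
promoter-rich, so a whole-genome null inflates enrichment relative to an
array-background-restricted null. The package implements the
whole-genome convention deliberately — it is the convention the global
ratio is defined with — and the hyper-vs-hypo permutation test is the
complementary analysis that is immune to this bias, since both subsets
share the array background. Interpret the global ratios with that caveat.

## What the synthetic generator emulates — and what it does not

`syntheticConfig()` describes a complete study: a genome of `nChroms`
equal chromosomes, `nGenes` non-overlapping gene regions with log-normal
lengths, and a probe table with configured per-(group, direction)
significant counts. The planted signal is the placement probability
$q = \min(1, \rho c)$ for significant hyper probes ($c$ = merged extended
track coverage fraction): with probability $q$ the probe lands uniformly
inside the track, otherwise uniformly outside, so the expected in-track
fraction is exactly $q$ and the measured enrichment ratio is an estimator
of $\rho$ with $O(c)$ bias (at $c = 0.05$ the bias is below 1%). That
closed-form link is what makes parameter-recovery tests exact rather than
eyeballed. Hypo-significant and non-significant probes are uniform over
the genome; positions are deduplicated so every probe occupies a distinct
base pair.

Default scale mirrors the motivating study design: 27,578 probes, 1,792
gene regions, ±2,000 bp flanks, per-group significant counts
(hyper/hypo) 20/83 fetal, 287/154 child, 1867/440 adult, planted
$\rho = 3$ — the magnitude of the adult-scale global enrichment reported
in that literature. The genome is 22 × 10 Mb: a scaled stand-in chosen so
the extended track covers about 5% of it, a realistic genome fraction
for ±2 kb-extended bivalent genes, while keeping simulation cheap.

The generator does **not** emulate array probe chemistry, beta-value
distributions, CpG-density covariation between probes and bivalent
domains, the promoter bias discussed above (probes are uniform, so the
whole-genome null is exactly calibrated in simulation — unlike on a real
array), correlated significance across age groups, or the age-regression
fitting itself (slopes and P-values are drawn, not fitted). Passing
tests therefore validate the *statistical machinery* — calibration,
parameter recovery, determinism — not the biological composition of real
array data.

## Validation strategy and problem sizes

The test suite checks, among others:

* overlap counting against a brute-force per-point, per-interval scan on
  1,000 random instances;
* the Monte Carlo permutation P against exhaustive enumeration of all
  label assignments for pooled sizes up to 12 (within three standard
  errors);
* type-I error of both tests at $\alpha = 0.05$ over 200 null runs at
  $n_{MC} = n_{perm} = 500$, against the exact binomial 99% interval —
  the track is built with ~20% coverage and 150 points per run so the
  discrete overlap statistic is fine-grained enough for the nominal level
  to be approachable;
* recovery of a planted $\rho = 3$ at 5% coverage within 10% of the
  truth, averaged over 50 replicate studies at the default study scale;
* conservation of the per-chromosome length and gap multisets on every
  null draw, and chi-squared uniformity of the single-segment start
  position over 1,000 draws at $\alpha = 0.001$.

These sizes are the package's chosen trade-off between statistical
resolution and a test suite that runs in minutes on one core; all of the
machinery accepts the conventional 50,000 draws for production analyses.

## Known limitations

* No liftover: all three inputs must share one assembly, and that is the
  user's responsibility to guarantee.
* No FDR-based filtering, no covariate-matched (CpG density,
  chromosome) permutation, no stratified nulls; the tests implemented are
  exactly the global track-randomization and the plain label-permutation
  designs.
* Strand is ignored throughout, appropriate for CpG methylation which is
  symmetric across strands.
* The empirical P floor means "P = 0.00002" at 50,000 draws should be
  read as "smaller than anything resolvable at this n", not as a point
  estimate.
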