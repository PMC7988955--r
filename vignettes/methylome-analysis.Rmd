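---
title: "Bacterial methylome profiling with bactometh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bacterial methylome profiling with bactometh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactometh)
```

## The problem

Single-molecule sequencing of a closed bacterial chromosome yields, after
signal-level modification calling, a per-site table: for every scorable
base, the strand, the read coverage, and the fraction of reads called as
modified. `bactometh` takes that table — together with the genome, its
annotation, and optional CRISPR/prophage intervals — and answers the
questions a methylome survey of a single circular chromosome asks:

* how methylated is each sequence context (Dam `GATC`, Dcm `CCWGG`, CpG,
  CHG, CHH), and how is that methylation distributed along the genome;
* do genes show the canonical depletion of methylation around
  transcription start and termination sites, and is there a gene subset
  with *elevated* promoter CpG methylation;
* are CRISPR arrays differentially methylated between spacers and
  repeats, and do any spacers self-target the host genome or its
  prophages;
* which sequence motifs are enriched around highly modified bases
  (the recognition sites of the active methyltransferases);
* how are genes distributed between strands along the chromosome, and
  does strand-biased gene placement co-vary with strand-specific CHH
  methylation.

Because raw signal data are rarely redistributable, the package also
contains a first-class synthetic-data generator that emits genomes,
annotations, CRISPR arrays and methylation tables with all of the above
structure planted under a fixed seed, so the whole pipeline is testable
end to end.

## Conventions

All internal coordinates are 1-based inclusive, matching how genome
positions are printed in annotation reports; BED/bedGraph output converts
to 0-based half-open at the boundary (`start - 1, end`). Circular
chromosomes are first-class: motif scanning, flanks, spacer mapping and
GC windows all wrap the origin. Annotation *features* spanning the origin
are rejected — printed gene tables for closed genomes do not use them,
and accepting them would make every interval operation ambiguous.

## Context scanning

`scan_contexts()` enumerates every scorable site on both strands:

* **Dam** (`GATC`) is palindromic: one duplex locus yields an adenine
  site on each strand.
* **Dcm** (`CCWGG`, W = A/T) is a self-complementary motif *set*; the
  scorable base is the second cytosine of each strand's 5'→3' reading.
* Remaining cytosines get **CpG**, **CHG** or **CHH** (H = A/C/T) by the
  trinucleotide rule, per strand.

Two rules are underdetermined by convention and fixed here explicitly:
cytosines inside a Dcm occurrence carry the Dcm label only (the
unscorable first C yields no site), and trinucleotide labels resolve with
precedence CpG > CHG > CHH. Any window containing `N` yields no site.
`context_census()` counts sites and distinct duplex loci per context;
CHH, being asymmetric, is also reported per strand. Because a methylome
summary table may count palindromic motifs once (duplex loci) or per
strand (sites), both counts are always reported.

## The per-context methylation statistic

The headline statistic is deliberately simple:

$$\text{methylation \%} = 100 \times
  \frac{\sum_i \text{fraction}_i}{N_\text{called}}$$

an *unweighted* mean of per-site modified fractions over called records —
the denominator is the number of called motifs, not the number of reads,
so deeply covered sites do not dominate. Sites are coverage-filtered
first (`filter_by_coverage()`): 30X for the motif-driven contexts
(CpG/Dcm/Dam), keep-everything (1X) for CHG/CHH, whose de novo calls are
not re-thresholded. The cutoff is inclusive. Quartiles of per-site
fractions (linear interpolation) accompany every mean, and both mean and
median coverage are printed because summary tables in the literature do
not always say which they use.

`bin_genome()` averages fractions in non-overlapping 100-kb bins; a bin
with no called site is `NA`, never 0 — the distinction matters precisely
where a context is depleted. CHH is split by strand so one-sided
depletion is visible. The partial final bin is kept at its true width.
A conservation property ties the two levels together: the global
statistic equals the site-count-weighted mean of bin values.

## Gene metaplots and promoter clustering

`gene_metaplot()` rescales every gene body to 100 windows and adds 50
fixed-width windows per 1-kb flank, orienting every row 5'→3' so column
1 is always distal upstream and the TSS sits at the column-50/51
boundary. A window's value is the mean fraction of called sites inside
it; windows without sites stay `NA`. Genes shorter than the number of
body bins are skipped (their body windows would be sub-base). Reading
the 1-kb normalization as a 100-window body makes a body window a
nominal 10 bp, which is the axis used to map promoter base-pair windows
to columns.

`cluster_promoters()` k-means-clusters the promoter-window columns
(TSS−200…TSS+50 bp by default, chosen to cover the −35 element) and
reports the cluster maximizing mean promoter methylation as the enriched
cluster. Choices made here, in the open: missing cells are imputed as 0
*only* inside the clustering step (statistics elsewhere never impute —
an uncalled promoter is evidence of nothing); `stats::kmeans`
(Hartigan–Wong) with 50 random restarts under a fixed seed stands in for
a k-means++ initialization, which at this data size gives the same
stability; `k = 6` by default to mirror the visual grouping of promoter
heatmaps, but the enriched-cluster definition (argmax of promoter mean)
keeps the reported gene set stable to `k`. For *recovery* benchmarks
against a single planted contrast we cluster at `k = 2`, where the
planted/background split is the model truth.

## CRISPR arrays

`parse_crispr_array()` finds repeat occurrences within a declared region
by Hamming matching (≤ 3 mismatches by default; `Biostrings::matchPattern`
is the search engine), picks the orientation once per array by best
total score, keeps a greedy non-overlapping left-to-right chain, and
calls the 15–60 bp gaps between consecutive repeats spacers. Larger gaps
warn — they indicate a split array. On a repeat-bounded region this
yields the invariant `spacers = repeats − 1`.

`array_methylation_profile()` tests spacer-vs-repeat methylation
periodicity with `T = mean(spacer-element means) − mean(repeat-element
means)` and a one-sided permutation p-value over element labels
(≥ 1,000 shuffles). A permutation test is the right tool at these sizes —
arrays have tens of elements, far too few for spectral methods.

`map_spacers()` slides every spacer over both strands of the full
circular genome (≤ 2 mismatches by default), discards hits overlapping
the source array, and flags hits inside prophage intervals — the
self-targeting test. For a random 35-bp spacer against a ~100-kb genome
the expected number of chance exact hits is ≈ 2·10⁵·4⁻³⁵, i.e. zero.

## De novo motif discovery

`select_modified_sites()` keeps sites of one base with fraction ≥ 0.5
and coverage ≥ 10; `enrich_kmers()` then counts every k-mer/offset pair
containing the modified base over strand-oriented ±4 bp windows and
compares against the same counts at *all* genomic occurrences of that
base on both strands. Using all same-base positions as background makes
composition bias cancel exactly — no shuffling needed. Enrichment is
`log2[((f+1)/(F+2)) / ((b+1)/(B+2))]`; significance is a one-sided
binomial test at the background rate, Bonferroni-corrected over tested
pairs at 0.01, and a motif must also be supported by at least 20
foreground sites. Candidates consistent on all shared positions relative
to the modified base collapse to the highest-scoring representative, so
a 4-bp recognition site inside a 5-mer window reports once. A genuinely
distinct second motif that happens to agree with the first on every
shared position would be absorbed — acceptable for motifs of this class,
and the trade is stated here rather than hidden.

## Genome structure

`strand_gene_counts()` bins genes per Mb by start coordinate (midpoint
available as a flag — the convention for boundary-spanning genes is not
standardized) and closes with a totals row. `gc_tracks()` computes
per-window GC content and GC skew `(G−C)/(G+C)` (0 where a window has no
G/C; windows wrap the origin on circular genomes).
`strand_bias_methylation_correlation()` reports the Spearman correlation
between per-bin strand-specific gene counts and same-strand CHH
methylation with a permutation p-value; with a handful of Mb-scale bins
on one chromosome this is intrinsically underpowered, so the sign is the
scientific content and the p-value is reported, flagged, and not
over-read.

## The synthetic-data generator

The generator is the package's substitute for raw signal data, and its
defaults *are* the study conditions the analysis targets:

* `simulate_genome()` — i.i.d. bases at 45% GC, with motif counts
  adjusted by substitution (never insertion, so coordinates stay stable)
  to a target ± 2%;
* `simulate_annotation()` — non-overlapping genes, lognormal lengths,
  per-Mb forward-strand probabilities so strand bias can be planted;
* `plant_crispr()` — alternating repeat/spacer blocks written by
  substitution, truth intervals returned;
* `simulate_methylome()` — every context site gets coverage
  ~ Poisson(λ) and fraction ~ Beta(μ, κ): per-context means
  μ = 0.764 (Dam), 0.0428 (CpG), 0.0381 (Dcm), 0.1741/0.1739 (CHH
  fwd/rev), coverages λ = 42/121/94/54, the values a deep-subsurface
  *Peptococcaceae* methylome survey reports. CHG, absent from such
  summary tables, defaults to μ = 0.04, λ = 54 (alongside the other
  low-methylation cytosine contexts). κ = 5 throughout: site-level
  dispersion is unpublished, so κ is a free shape parameter, not an
  estimate — at κ = 5 low-mean contexts are strongly right-skewed and
  Dam is bimodally high, qualitatively matching published distribution
  plots. κ = Inf degenerates to exact means and is used in tests.
* structured effects: reverse-strand CHH means ×0.2 inside a depletion
  segment; +0.3 CpG boost in the promoter windows of a planted gene
  cluster; CHH means of 0.4/0.02 inside spacers/repeats of planted
  arrays.

`simulate_dataset()` wires these together into the `dri13` preset: a
3.8 Mb-equivalent chromosome scaled by `scale` (default 0.1, i.e.
380 kb — large enough for every census to have thousands of sites,
small enough to simulate in seconds), planted GATC density matching the
published Dam motif count, per-Mb strand bias from the published strand
table (forward fractions 0.69, 0.17, 0.39, 0.82), both published repeat
sequences as planted arrays at proportionally scaled locations,
prophage intervals at scaled published starts, CHH depletion in the
reverse-gene-rich second Mb-equivalent segment, and a promoter-boosted
cluster of `45 × scale` genes. Everything is deterministic under one
seed.

What the generator does *not* emulate, and hence what passing tests do
not show: read-level error structure and mapping bias (the model is
per-site), sequence autocorrelation beyond planted motifs (real genomes
are not i.i.d.), operon structure and overlapping genes, and the true
site-level dispersion of any real methylome. Tests on this data
establish that the estimators recover what was planted under the model —
not that the model is the truth of any particular organism.

## Numerical choices and degenerate inputs

Permutation p-values use the add-one estimator `(1 + #{T* ≥ T}) / (B + 1)`,
so they are never exactly zero. Quartiles use R's default linear
interpolation. Zero called records for a context is an explicit error,
not 0%. K-means with fewer distinct rows than `k` reduces `k` to the
number of distinct rows (all-identical input collapses to one cluster).
Bins and elements without sites are `NA` and excluded with a warning
from summary statistics. Beta means are clipped to (0, 1) by 1e-9
before sampling. Every seeded function restores the caller's RNG state.

## Problem sizes used in the shipped checks

Recovery of the per-context means uses 5,000 sites per context over 200
seeded replicates (tolerance ±1.0 percentage point, ≥ 95% of
replicates). Promoter-cluster recovery plants 45 genes of 1,000 at
boost 0.3 over 50 seeds (precision and recall ≥ 0.9). The scanner is
checked against an independent per-position oracle on 200 random 5-kb
sequences. Motif recovery plants 400 copies each of `GAACT`/`CCGG` in
200 kb; the null false-positive rate uses 100 seeds on 50 kb. These
sizes make the full suite run in a couple of minutes on one core while
keeping every Monte-Carlo margin wide.

## Known limitations

Origin-spanning annotation features are rejected (v1). The CRISPR
parser assumes a repeat consensus is known; it does not discover arrays
de novo. Motif discovery reports fixed-length k-mer consensi, not
position weight matrices, and cannot separate two motifs that agree on
all shared positions. Accession-based checks against the real assembly
require the user to download it; nothing in the package fetches data
from the network.

## A short worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(seed = 7, scale = 0.05)
rec <- filter_by_coverage(ds$records)
context_summary_table(rec)

arr <- parse_crispr_array(ds$genome, ds$arrays[[1]]$region,
                          dri13_reference()$arrays$array1$repeat_seq)
array_methylation_profile(arr, rec)$p_value
```
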