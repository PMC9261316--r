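---
title: "Detecting mosaic somatic SNVs across tissues: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mosaic somatic SNVs across tissues: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicsnv)
```

## The problem

A post-zygotic (mosaic) single-nucleotide variant is present in only a
fraction of an individual's cells, so it appears in sequencing data at a
variant allele frequency (VAF) well below the 50% expected of a germline
heterozygote — often below 15% in blood and below 1% in solid tissues. At
ordinary exome depth (~60X) such variants are indistinguishable, read by
read, from the three dominant confounders:

* **germline heterozygous SNVs**, whose alt counts follow Binomial(depth, 0.5);
* **mapping artifacts** from copy-number variable or unresolved regions,
  where reads from a paralogous locus collapse onto one reference copy; and
* **recurrent sequencing or alignment errors** that reappear across
  unrelated individuals.

Without a matched normal sample, the only way to separate these classes is
to model the read-level signatures each one leaves. `mosaicsnv` implements
a battery of per-site statistical filters over read evidence, combines
them across the multiple tissues of an individual, tests candidate sites
against an external allele-count panel, applies the decision rules used in
amplicon ultra-deep validation, and summarises validated variants as a
96-category trinucleotide mutational spectrum.

## Per-site filters

Each filter interrogates one failure mode. For a site with `ad_alt` alt
reads out of `d` informative (ref+alt) reads:

* **Germline binomial test.** Under the germline hypothesis
  `ad_alt ~ Binomial(d, 1/2)`. The exact two-sided test must be
  *significant* (p < `-b`, default 0.05) for the site to count as somatic;
  non-significance is germline-consistent. At `d = 60` this controls the
  rate at which true hets masquerade as somatic below the alpha level (the
  test is discrete, so the realised rate is ~0.03).
* **Strand balance.** Forward/reverse alt counts are compared with the
  classical exact equality-of-two-Poisson-rates construction: conditional
  on the total, the forward count is Binomial(total, 1/2). Here
  *non-significance* is required (`-sp`), and a hard ratio bound
  (`max/min < 2`, pseudo-count 1 in the denominator) catches small-count
  imbalance the test cannot. A consequence worth knowing: with the strict
  ratio bound at 2, three supporting reads can never pass (best split 2:1),
  so a single-sample-detectable variant effectively needs four balanced
  alt reads.
* **Read-pair balance** (`-pr`): the same ratio construction over
  first/second mate counts.
* **Position-in-reads (PIR) score.** Collapsed-paralog alignments place the
  alternative allele near read ends. The score sums four boolean
  sub-checks of an allele's normalized read positions (median inside
  [0.2, 0.8]; at most half the observations within 0.1 of an end; at least
  two distinct positions unless there is exactly one observation; a
  two-sided rank-sum test against the other allele non-significant, with
  auto-pass below 3 observations). A site needs `-pir 4,4`: both alleles
  unbiased. The sub-score construction is this package's; only the passing
  value (4) is fixed by convention, and all four sub-thresholds are
  arguments.
* **Clipping, mapping-quality and mismatch imbalance.** Per-allele
  clipped-read fractions may differ by at most `-clip` (strict, with a 1e-9
  epsilon so a difference that *is* the threshold up to floating-point
  representation counts as the boundary); per-read mapping qualities and
  mismatch counts are compared between alleles with two-sided Mann-Whitney
  tests that must be non-significant (`-mq`, `-mm`), auto-passing when
  either allele has fewer than 3 reads — imbalance cannot be assessed on
  two reads, and failing closed there would systematically reject true
  low-VAF somatics.
* **Hard thresholds**: `ad_alt >= 2` (combined) or `>= 3` (single sample);
  `VAF < 0.5`; depth in [20, 100] inclusive; quality-filtered recount VAF
  `< 0.4` (bases/reads below BQ 20 / MQ 20 are excluded from the recount —
  those floors are not printed in the parameter vocabulary and are exposed
  as configuration fields); at most 4 other variants within one read
  length; fewer than 4 local haplotypes; no overlapping CNV call in that
  sample (`-cnv NO`).

Haplotype counting uses the allele strings of reads spanning the site and
its in-phase neighbours; a string must be supported by at least two reads,
which keeps single sequencing errors from creating phantom haplotypes. A
site with only ref and alt reads and no phased neighbour therefore counts
2 haplotypes.

All "<" thresholds are strict and the depth range is inclusive, matching
the way the bounds are stated. Every statistical filter fails closed on
empty input (no reads, zero depth), except the explicitly documented
small-sample auto-passes.

## Combined, single and both

True somatics shared across tissues may fail individual filters in
individual samples by chance. The combined criterion (`-c COMBINED -ns n`)
requires that **every filter be passed by at least n of the individual's
samples, allowing a different passing set per filter**. `-c SINGLE`
requires one sample to pass everything (with the higher alt-depth floor),
and `-c BOTH` (the default) accepts either. The default asks 4 of 5
tissues per filter. A variant with two clean alt reads in each of five
tissues illustrates the mechanism: every per-filter count is 5 >= 4, so
COMBINED accepts it, while no single tissue reaches the 3-read
single-sample floor.

## Panels

Two recurrence checks operate across individuals:

* **Cohort recurrence**: a candidate supported by reads in any other
  individual of the same cohort (any sample with >= 1 alt read, the support
  threshold being configurable) is presumed germline or artifactual; by
  default no supporting individual is tolerated.
* **Beta-binomial panel of normals.** The external panel provides
  per-individual allele counts (k_i, n_i) at the site. We fit a
  beta-binomial error model — method of moments on the pooled rate and the
  variance of per-individual rates; a plain pooled-rate binomial when the
  panel variance is at or below binomial (with a half-count pseudo-count so
  an all-zero panel keeps a proper, near-zero rate rather than a degenerate
  one); maximum likelihood via `optim` when moments give non-positive
  shapes — and require the observation's upper-tail probability
  P(X >= k_obs) to be significant (`-pon`). The test is upper-tail only:
  panel support marks artifacts and germline sites, and a true somatic
  shows excess over near-zero panel noise. A site absent from the panel
  auto-passes with a `no_pon` annotation by default (policy-controlled).
  Sites with no alt support get p = 1 by definition.

The panel table schema (long TSV: individual, chrom, pos, ref, A, C, G, T)
is this package's; real panels are usually private and arrive in
institution-specific formats, so the reader is deliberately minimal.

## Masks

The non-callable set removes sites off-target, in the accessibility
("strict") mask, in segmental duplications, in low-mappability or
homopolymer regions, within 5 bp of an indel (a site exactly 5 bp away is
removed; 6 bp is kept), or in the depth-exclusion set. Depth exclusion
keeps the central 75% of the cohort depth distribution with symmetric
12.5% tails, computed with type-7 quantiles and strict inequalities — so a
table of tied depths excludes nothing and `keep_fraction = 1` is empty.
Whether the original procedure pooled depths across samples or worked
per sample is not derivable from its description; this implementation pools
by default and the depth table is an explicit input, so per-sample tables
can be supplied instead. CNV calls are deliberately *not* part of the
global mask: they are per-sample evidence, evaluated inside the filter
battery, because a CNV in one tissue says nothing about the others.

## Amplicon validation

Ultra-deep amplicon resequencing (~18,000X) can confirm VAFs far below
exome sensitivity. A candidate is validated in a sample when (1) its alt
allele is that sample's second most common allele — ties at rank 2 count,
and an allele that drifted above 50% still satisfies the rule — and
(2) its VAF strictly exceeds mean + 2 sd of the alt VAFs in all
coverage-sufficient samples of *other* individuals. Coverage sufficiency
is depth >= mean - 1 sd over all samples at the amplicon; the candidate
individual's own tissues are excluded from the background so a
multi-tissue mosaic cannot inflate its own threshold. Standard deviations
use the n-1 denominator. Sites validated in >= 2 tissues with all validated
VAFs > 30% are reclassified germline heterozygous; otherwise the class is
somatic_multi_tissue, somatic_single_tissue or false_positive by the count
of validated tissues. Classification is invariant to tissue order.

## Mutational spectrum

Validated substitutions are classified into the 96 pyrimidine-centered
categories (6 substitution types x 16 flanking contexts, alphabetical
within blocks — the conventional ordering, fixed by `sbs96_categories()`).
Purine-reference variants are reverse-complemented together with their
context, so the classification is involutive over strand representation
(checked exhaustively over all 192 raw combinations). The spectrum is
correlated (Pearson, on proportions; Pearson is location/scale invariant
so counts give the same r) against a signature matrix supplied as input.
The bundled matrix in `inst/extdata/signatures_synthetic.tsv` is
**synthetic**: five columns with the qualitative shapes of well-known
signature families (CpG deamination, flat clock-like, dipyrimidine C>T,
C>A-heavy, uniform), built for tests and examples. It is not the COSMIC
matrix; analyses of real data should supply the licensed matrix of their
chosen version, which this module is agnostic to.

## The simulator

`sim_scenario()`/`simulate_cohort()` generate the full input surface —
reference, candidates, per-read evidence, masks, panel, depth table,
cohort support, amplicon counts — under one seed, with a truth table
mapping each planted site to its class and, for artifacts, to the filter
designed to reject it. Defaults encode the study design the filters
assume: 10 individuals x 5 tissues (blood + 4 brain regions) at 60X,
100 bp reads, somatic VAF 11.5% in blood vs 0.7% in brain, 18,000X
amplicons, a 100-individual panel, and a 100-site truth of 80 germline,
5 somatic and 3 sites in each artifact class.

Choices that matter when interpreting test results:

* **Clean reads are idealized.** Strands and mates alternate, positions
  sit on an even grid, qualities are constant and mismatch counts exclude
  the candidate base itself. Real libraries are noisier in every one of
  these; the idealization makes the designated filter the *only* rejection
  route for each artifact class, which is what the planted-truth checks
  need. Passing them shows the decision logic is right, not that the
  thresholds are optimal on real data.
* **Planted somatics are drawn inside the sensitivity envelope.** The
  carrier (blood) alt count is a truncated binomial at >= 4 supporting
  reads. An untruncated draw occasionally yields 2-3 alt reads, which no
  configuration with a strand-ratio bound of 2 can accept single-sample —
  such a site is real but undetectable, and planting it would test the
  generator, not the filters.
* **Germline sites are population SNPs.** They segregate in the external
  panel and the cohort at a frequency drawn from [0.1, 0.4], which is why
  the panel tests catch the (rare) germline draws that fool the binomial
  test. A private germline variant absent from every panel is not
  simulated; against such a site only the binomial/VAF filters act.
* **The depth background is overdispersed** (negative binomial, size 3),
  emulating capture-efficiency variation, so the central-75% band spans
  ordinary coverage and the depth-exclusion mask removes only genuine
  extremes. On a homogeneous Poisson background the same rule would
  discard a quarter of perfectly normal sites.
* **The cohort support summary carries true variant support only.**
  Sporadic single-read errors in other individuals are below the summary,
  matching the support definition (>= 1 alt read of a segregating variant);
  an error-aware support model would instead motivate a higher support
  threshold, which the configuration exposes.
* The simulator emits per-read evidence tables, not alignments; mismatch
  and clipping behaviour is planted at the feature level. No indel errors
  are simulated (indel handling is out of scope; near-indel artifacts are
  planted via the mask input).

## Problem sizes and runtime

The shipped tests run the full 100-site default cohort once, exhaust the
exact-test oracle to n = 200, use 10,000 replicates for the type-I check
and 4,000-5,000 individuals per depth for the joint-vs-single comparison,
and draw 1,000 variants for the spectrum recovery — sizes chosen so the
whole suite completes in about two minutes on one core while keeping every
binomial standard error an order of magnitude below the margins being
asserted.

## Known limitations

* The pipeline evaluates SNVs only; indels are consumed as masks, never
  called.
* Read evidence arrives as the documented per-read TSV; BAM/CRAM
  extraction is left to upstream annotators.
* The PIR sub-score construction and the panel-table schema are this
  package's own; other implementations of the same ideas may draw slightly
  different boundaries at single sites.
* The beta-binomial moment fit uses the mean panel depth in the
  overdispersion equation; with wildly heterogeneous panel depths the ML
  fallback is the safer route (it engages automatically when moments
  misbehave).
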