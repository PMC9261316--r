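# mosaicsnv

Detection of mosaic (post-zygotic) somatic single-nucleotide variants from
**unpaired multi-tissue sequencing data** — for studies that sequence
several tissues of the same individuals (e.g. blood plus brain regions)
without matched normals, where candidate calls from a lax upstream caller
must be separated from germline heterozygotes, collapsed-mapping artifacts
and recurrent errors.

## What it implements

A candidate site with `ad_alt` alt reads out of `d` informative reads is
evaluated by a battery of per-site filters:

* **Germline test** — exact binomial test of `ad_alt ~ Bin(d, ½)`;
  significance (p < 0.05) rejects heterozygosity and supports somatic
  origin.
* **Strand and pair balance** — the exact conditional-binomial comparison
  of two Poisson counts (non-significance required) plus strict count-ratio
  bounds (strand < 2, pair < 4, pseudo-count 1).
* **Position-in-reads (PIR) score** — a 0–4 score of whether an allele's
  supporting bases cluster at read ends (the collapsed-paralog signature);
  both alleles must score 4.
* **Imbalance tests** — Mann–Whitney comparisons of per-read mapping
  quality and mismatch counts between alleles, and a clipped-read-fraction
  difference bound.
* **Hard thresholds** — alt depth (2 combined / 3 single-sample), VAF < 0.5,
  depth in [20, 100], recount VAF < 0.4, ≤ 4 nearby variants, < 4 local
  haplotypes, no overlapping CNV call.
* **Cohort & panel recurrence** — no alt support in other cohort
  individuals, and a **beta-binomial panel-of-normals test**: fit
  BetaBin(a, b) to the panel's per-individual counts (k_i, n_i) and require
  P(X ≥ k_obs) < 0.05.

Decisions are taken per individual in `SINGLE`, `COMBINED` (every filter
passed by ≥ n of the individual's tissues, with possibly different tissues
per filter) or `BOTH` mode. The default configuration is the parameter
string

```
-c BOTH -ns 4 -ad 2 -adss 3 -vaf 0.5 -dp1 20 -dp2 100 -sr 2 -pr 4 -sp 0.05
-b 0.05 -nrl 4 -hap 4 -cnv NO -pir 4,4 -vafq 0.4 -clip 0.9 -mq 0.05
-mm 0.05 -pon 0.05
```

so `parse_config("")` reproduces it with zero flags. Downstream modules
implement amplicon ultra-deep validation (rank-2 allele rule, background
mean + 2 sd exceedance, germline reclassification at VAF > 30%) and the
96-category trinucleotide mutational spectrum with signature correlation.
A seeded simulator generates full synthetic cohorts — evidence, masks,
panel, amplicons — with planted truth, so everything is testable without
external data.

## Worked example

```r
library(mosaicsnv)

scn <- sim_scenario(seed = 11, n_individuals = 4, n_germline = 12,
                    n_somatic = 2, n_artifacts_per_class = 1)
sim <- simulate_cohort(scn)
run <- run_filter(sim$candidates, sim$evidence, sim$masks, sim$pon,
                  cfg = parse_config(""), cohort_support = sim$cohort_support)
run$manifest$counts
#> $candidate_units
#> [1] 19
#> $non_callable
#> [1] 2
#> $evaluated
#> [1] 17
#> $failed
#> [1] 15
#> $survivors
#> [1] 2

subset(run$decisions, final_pass)[, c("site_key", "individual_id",
                                      "single_pass", "combined_pass")]
#>       site_key individual_id single_pass combined_pass
#> 9  1:11800:G>A          ind2        TRUE         FALSE
#> 11 1:14200:C>G          ind2        TRUE         FALSE
```

The 19 candidate (site × individual) units telescope into 2 non-callable
(masked), 15 failed and 2 survivors — and the two survivors are exactly
the two planted somatic variants of the scenario (`sim$truth` confirms;
the 12 germline and 5 artifact sites are all rejected). Individual filters
are available directly:

```r
binomial_germline_test(6, 60)
#> p = 9.72e-11, pass = TRUE   # 6/60 alt reads are not a heterozygote
```

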