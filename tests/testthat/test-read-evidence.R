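test_that("normalized read position maps read ends to 0 and 1", {
  expect_equal(normalized_position(0L, 100L), 0)
  expect_equal(normalized_position(99L, 100L), 1)
  expect_equal(normalized_position(49L, 99L), 0.5)
  expect_equal(normalized_position(0L, 1L), 0)
})

test_that("nearby-variant counting is inclusive at one read length", {
  expect_equal(count_nearby_variants(1000L, integer(0), 100L), 0L)
  expect_equal(count_nearby_variants(1000L, c(1100L, 1101L), 100L), 1L)
  expect_equal(count_nearby_variants(1000L, 1000L + c(-40L, -10L, 5L, 20L, 50L), 100L), 5L)
})

test_that("haplotype counting requires two supporting reads per pattern", {
  # site alone, both alleles present
  expect_equal(count_haplotypes(c("ref", "ref", "alt", "alt")), 2L)
  # full combinatorial case with one nearby het
  haps <- rep(c("R,R", "R,A", "A,R", "A,A"), each = 2)
  expect_equal(count_haplotypes(haps), 4L)
  # a single-read pattern is excluded
  expect_equal(count_haplotypes(c(rep("R,R", 3), rep("R,A", 2), "A,A")), 2L)
  # reads not spanning all positions are dropped
  expect_equal(count_haplotypes(c("R,R", "R,R", NA, NA)), 1L)
  expect_equal(count_haplotypes(character(0)), 0L)
})

test_that("evidence aggregation matches direct pileup arithmetic", {
  site <- one_site()
  obs <- make_clean_obs(30, 30)
  ev <- collect_evidence(site, obs)
  expect_equal(ev$ad_ref, 30L); expect_equal(ev$ad_alt, 30L)
  expect_equal(ev$vaf, 0.5); expect_equal(ev$depth, 60L)

  obs2 <- make_clean_obs(58, 2, alt_strands = c("+", "+"))
  ev2 <- collect_evidence(site, obs2)
  expect_equal(ev2$fwd_alt, 2L); expect_equal(ev2$rev_alt, 0L)
})

test_that("low-quality bases stay in raw depth but leave the recount VAF", {
  site <- one_site()
  obs <- make_clean_obs(58, 2)
  obs$base_quality[obs$allele == "alt"] <- 10L  # below the recount floor
  ev <- collect_evidence(site, obs, min_base_quality = 20L)
  expect_equal(ev$ad_alt, 2L)
  expect_equal(ev$vaf, 2 / 60)
  expect_equal(ev$vaf_recount, 0)  # recount numerator excludes the two alt reads
  expect_equal(ev$depth, 60L)
})

test_that("zero overlapping reads yield a depth-0 evidence object", {
  site <- one_site()
  ev <- collect_evidence(site, make_clean_obs(0, 0))
  expect_equal(ev$depth, 0L)
  expect_equal(ev$vaf, 0)
})

test_that("evidence equals brute-force per-read enumeration on random pileups", {
  set.seed(303)
  site <- one_site()
  for (i in seq_len(1000)) {
    n <- sample(5:40, 1)
    obs <- data.frame(
      chrom = "1", pos = 5000L, sample_id = "s1",
      allele = sample(c("ref", "alt", "other"), n, replace = TRUE, prob = c(.6, .3, .1)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      mate = sample(c("R1", "R2"), n, replace = TRUE),
      pos_in_read = sample(0:99, n, replace = TRUE),
      read_length = 100L,
      mapping_quality = sample(0:60, n, replace = TRUE),
      n_mismatches = rpois(n, 1),
      is_clipped = rbinom(n, 1, 0.2),
      base_quality = sample(2:40, n, replace = TRUE),
      stringsAsFactors = FALSE)
    ev <- collect_evidence(site, obs, min_base_quality = 20L, min_mapping_quality = 20L)

    is_ref <- obs$allele == "ref"; is_alt <- obs$allele == "alt"
    expect_identical(ev$depth, n)
    expect_identical(ev$ad_ref + ev$ad_alt + sum(obs$allele == "other"), n)
    expect_identical(ev$ad_ref, sum(is_ref))
    expect_identical(ev$fwd_alt, sum(is_alt & obs$strand == "+"))
    expect_identical(ev$rev_alt, sum(is_alt & obs$strand == "-"))
    expect_identical(ev$ad_alt, ev$fwd_alt + ev$rev_alt)
    expect_identical(ev$r1_alt, sum(is_alt & obs$mate == "R1"))
    hq <- obs$base_quality >= 20 & obs$mapping_quality >= 20
    num <- sum(is_alt & hq); den <- sum((is_ref | is_alt) & hq)
    expect_equal(ev$vaf_recount, if (den > 0) num / den else 0)
    expect_equal(length(ev$pir_positions_alt), ev$ad_alt)
    expect_equal(ev$mm_ref, obs$n_mismatches[is_ref])
    if (ev$ad_ref > 0) expect_equal(ev$clip_frac_ref, mean(obs$is_clipped[is_ref] == 1))
    expect_true(ev$vaf >= 0 && ev$vaf <= 1)
  }
})
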