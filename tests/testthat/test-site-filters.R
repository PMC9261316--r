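test_that("germline binomial test matches exact tail enumeration", {
  b <- binomial_germline_test(30, 60)
  expect_equal(b$p_value, 1)
  expect_false(b$pass)  # perfectly balanced: germline-consistent

  b2 <- binomial_germline_test(2, 60)
  expect_equal(b2$p_value, 3.1762786845135e-15, tolerance = 1e-10)
  expect_true(b2$p_value < 1e-10)
  expect_true(b2$pass)

  b3 <- binomial_germline_test(24, 60, alpha = 0.05)
  expect_equal(b3$p_value, 0.15500190400326, tolerance = 1e-10)
  expect_false(b3$pass)

  expect_false(binomial_germline_test(0, 0)$pass)  # fails closed
})

test_that("strand Poisson test is the exact conditional binomial comparison", {
  s <- poisson_strand_test(5, 5)
  expect_equal(s$p_value, 1)
  expect_true(s$pass)

  s2 <- poisson_strand_test(12, 0, alpha = 0.05)
  expect_equal(s2$p_value, 2 * 0.5^12)
  expect_false(s2$pass)

  s3 <- poisson_strand_test(3, 1, alpha = 0.05)
  expect_equal(s3$p_value, 0.625)
  expect_true(s3$pass)

  expect_false(poisson_strand_test(0, 0)$pass)
})

test_that("both exact tests agree with brute-force enumeration at small n", {
  for (n in 1:40) {
    d <- dbinom(0:n, n, 0.5)
    oracle <- vapply(0:n, function(k) sum(d[d <= d[k + 1] * (1 + 1e-7)]), numeric(1))
    got_b <- vapply(0:n, function(k) binomial_germline_test(k, n)$p_value, numeric(1))
    got_s <- vapply(0:n, function(k) poisson_strand_test(k, n - k)$p_value, numeric(1))
    expect_equal(got_b, oracle, tolerance = 1e-12)
    expect_equal(got_s, oracle, tolerance = 1e-12)
  }
})

test_that("ratio filters use the pseudo-count and strict bounds", {
  expect_true(strand_ratio(4, 4, 2)$pass)
  r <- strand_ratio(6, 3, 2); expect_equal(r$ratio, 2); expect_false(r$pass)
  r2 <- strand_ratio(3, 0, 2); expect_equal(r2$ratio, 3); expect_false(r2$pass)

  expect_true(pair_ratio(2, 2, 4)$pass)
  p <- pair_ratio(4, 1, 4); expect_equal(p$ratio, 4); expect_false(p$pass)
  p2 <- pair_ratio(0, 3, 4); expect_equal(p2$ratio, 3); expect_true(p2$pass)
})

test_that("position-in-reads score rewards unbiased placements", {
  spread <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_equal(pir_score(spread, spread + 0.02), 4L)
  expect_lte(pir_score(runif(10, 0, 0.05), spread), 2L)  # end-clustered
  expect_equal(pir_score(0.5, spread), 4L)               # singleton rule
  expect_equal(pir_score(numeric(0), spread), 0L)
})

test_that("clip difference is absolute with a strict bound", {
  expect_true(clip_difference(0, 0)$pass)
  d <- clip_difference(0.05, 0.95, 0.9)
  expect_equal(d$difference, 0.9); expect_false(d$pass)
  expect_true(clip_difference(0.2, 0.5)$pass)
  expect_false(clip_difference(NA_real_, 0.5)$pass)
})

test_that("allele rank test flags imbalance and auto-passes tiny alleles", {
  ident <- allele_rank_test(rep(c(10, 20, 30), 4), rep(c(10, 20, 30), 4))
  expect_true(ident$pass)
  imb <- allele_rank_test(rep(60, 10), rep(0, 10), alpha = 0.05)
  expect_equal(imb$p_value, 1.593791e-05, tolerance = 1e-5)
  expect_false(imb$pass)
  expect_true(allele_rank_test(rep(60, 10), c(0, 0))$pass)   # n < 3 auto-pass
  expect_false(allele_rank_test(numeric(0), 1:5)$pass)       # empty fails closed
})

test_that("binomial p-value is monotone as alt depth moves away from balance", {
  for (d in c(20L, 60L, 100L)) {
    p <- vapply(floor(d / 2):0, function(k) binomial_germline_test(k, d)$p_value, numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("type-I error of the germline filter is controlled at depth 60", {
  set.seed(101)
  k <- rbinom(10000, 60, 0.5)
  p_by_k <- vapply(0:60, function(kk) binomial_germline_test(kk, 60)$p_value, numeric(1))
  rate <- mean(p_by_k[k + 1] < 0.05)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("the battery produces one entry per criterion and a conjunction", {
  cfg <- filter_config()
  site <- one_site()
  panel <- zero_panel()

  ev <- collect_evidence(site, make_clean_obs(54, 6))
  v <- threshold_battery(ev, cfg, single_sample = FALSE, panel = panel)
  expect_setequal(v$results$filter,
                  c("alt_depth", "vaf", "depth_range", "vaf_recount", "strand_ratio",
                    "pair_ratio", "strand_poisson", "germline_binomial",
                    "nearby_variants", "haplotypes", "cnv", "pir_ref", "pir_alt",
                    "clip_diff", "mq_rank", "mismatch_rank", "pon"))
  expect_equal(anyDuplicated(v$results$filter), 0L)
  expect_identical(v$overall_pass, all(v$results$pass))
  expect_true(v$overall_pass)  # clean somatic fixture passes everything

  # single-sample alt-depth threshold
  ev2 <- collect_evidence(site, make_clean_obs(58, 2))
  v2 <- threshold_battery(ev2, cfg, single_sample = TRUE, panel = panel)
  expect_false(v2$results$pass[v2$results$filter == "alt_depth"])
  v2c <- threshold_battery(ev2, cfg, single_sample = FALSE, panel = panel)
  expect_true(v2c$results$pass[v2c$results$filter == "alt_depth"])

  # depth boundary is inclusive at 20, exclusive below
  ev3 <- collect_evidence(site, make_clean_obs(15, 4))
  v3 <- threshold_battery(ev3, cfg, panel = panel)
  expect_false(v3$results$pass[v3$results$filter == "depth_range"])
  ev4 <- collect_evidence(site, make_clean_obs(16, 4))
  v4 <- threshold_battery(ev4, cfg, panel = panel)
  expect_true(v4$results$pass[v4$results$filter == "depth_range"])

  # CNV overlap fails its criterion; disabling the flag removes the entry
  v5 <- threshold_battery(ev, cfg, cnv_overlap = TRUE, panel = panel)
  expect_false(v5$results$pass[v5$results$filter == "cnv"])
  cfg_off <- filter_config(require_no_cnv = FALSE)
  v6 <- threshold_battery(ev, cfg_off, cnv_overlap = TRUE, panel = panel)
  expect_false("cnv" %in% v6$results$filter)
})
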