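filters5 <- c("a", "b", "c", "d", "e")

verdict_from_row <- function(passes) {
  stub_verdict(setNames(as.list(passes), filters5))
}

test_that("combined decision allows different passing sample sets per filter", {
  tissues <- c("bl", "cb", "cx", "sn", "st")
  # filter a passed by {bl,cb,cx,sn}, filter b by {bl,cb,cx,st}, rest by all
  pass <- sapply(tissues, function(s) c(
    a = s %in% c("bl", "cb", "cx", "sn"),
    b = s %in% c("bl", "cb", "cx", "st"),
    c = TRUE, d = TRUE, e = TRUE))
  verdicts <- lapply(tissues, function(s) verdict_from_row(pass[, s]))
  names(verdicts) <- tissues
  expect_true(combined_decision(verdicts, 4))

  # one filter passed by only 3 samples
  pass["c", c("sn", "st")] <- FALSE
  verdicts2 <- lapply(tissues, function(s) verdict_from_row(pass[, s]))
  expect_false(combined_decision(verdicts2, 4))

  expect_true(combined_decision(verdicts2, 0))
  expect_warning(res <- combined_decision(verdicts, 6), "exceeds")
  expect_false(res)
})

test_that("combined decision equals brute force on random verdict matrices", {
  set.seed(55)
  for (i in 1:200) {
    ns <- sample(2:6, 1); nf <- sample(2:8, 1); nr <- sample(0:ns, 1)
    m <- matrix(runif(ns * nf) < 0.7, nrow = nf)
    fl <- paste0("f", seq_len(nf))
    verdicts <- lapply(seq_len(ns), function(j)
      stub_verdict(setNames(as.list(m[, j]), fl)))
    expect_identical(combined_decision(verdicts, nr),
                     all(rowSums(m) >= nr) || nr == 0)
  }
})

test_that("mode resolution combines the single and combined legs", {
  cfg <- filter_config(combined_mode = "BOTH", n_samples_per_ind = 4L)
  # one tissue passes everything, others fail one filter each
  vs <- list(bl = verdict_from_row(rep(TRUE, 5)),
             cb = verdict_from_row(c(FALSE, TRUE, TRUE, TRUE, TRUE)),
             cx = verdict_from_row(c(TRUE, FALSE, TRUE, TRUE, TRUE)),
             sn = verdict_from_row(c(TRUE, TRUE, FALSE, TRUE, TRUE)),
             st = verdict_from_row(c(TRUE, TRUE, TRUE, FALSE, TRUE)))
  dec <- resolve_mode(vs, vs, cfg)
  expect_true(dec$single_pass)
  expect_true(dec$combined_pass)  # every filter still has >= 4 passes
  expect_true(dec$final_pass)

  # rotating failures: 4 of 5 pass per filter but nobody passes all filters
  rot <- lapply(1:5, function(i) {
    p <- rep(TRUE, 5); p[i] <- FALSE; verdict_from_row(p)
  })
  names(rot) <- names(vs)
  dec2 <- resolve_mode(rot, rot, cfg)
  expect_false(dec2$single_pass)
  expect_true(dec2$combined_pass)
  expect_true(dec2$final_pass)
  dec2s <- resolve_mode(rot, rot, filter_config(combined_mode = "SINGLE"))
  expect_false(dec2s$final_pass)

  # zero passes anywhere
  none <- lapply(1:5, function(i) verdict_from_row(rep(FALSE, 5)))
  names(none) <- names(vs)
  dec3 <- resolve_mode(none, none, cfg)
  expect_false(dec3$final_pass)
})

test_that("cohort recurrence tolerates at most the configured individuals", {
  expect_true(panel_recurrence(logical(0))$pass)
  expect_true(panel_recurrence(rep(FALSE, 9))$pass)
  expect_false(panel_recurrence(c(TRUE, TRUE, TRUE, rep(FALSE, 6)))$pass)
  expect_true(panel_recurrence(c(TRUE, rep(FALSE, 8)), max_recurrence = 1L)$pass)
})

test_that("beta-binomial fit follows the documented fallback chain", {
  # zero-variance panel -> pooled binomial with pseudo-count
  f <- fit_betabinomial(rep(0L, 50), rep(60L, 50))
  expect_identical(f$method, "binomial")
  expect_equal(f$p, 0.5 / 3001)
  # homogeneous noisy panel (all k identical) -> variance 0 <= binomial
  f2 <- fit_betabinomial(rep(6L, 50), rep(60L, 50))
  expect_identical(f2$method, "binomial")
  expect_equal(f2$p, 300.5 / 3001)
  # overdispersed panel -> beta-binomial by moments
  f3 <- fit_betabinomial(c(rep(0L, 30), rep(12L, 20)), rep(60L, 50))
  expect_identical(f3$method, "betabinom")
  expect_true(f3$a > 0 && f3$b > 0)
  expect_error(fit_betabinomial(0L, 60L), "2 individuals")
})

test_that("beta-binomial tail summation matches the integration oracle", {
  for (ab in list(c(0.5, 30), c(2, 50), c(1, 1), c(5, 5))) {
    for (k in c(1, 3, 6, 12)) {
      expect_equal(pbetabinom_upper(k, 60, ab[1], ab[2]),
                   betabinom_tail_oracle(k, 60, ab[1], ab[2]), tolerance = 1e-8)
    }
  }
  expect_equal(pbetabinom_upper(0, 60, 1, 10), 1)
  expect_equal(pbetabinom_upper(61, 60, 1, 10), 0)
})

test_that("panel test separates clean somatics from recurrent artifacts", {
  # clean somatic over an all-zero panel: highly significant
  clean <- betabinomial_pon_test(6, 60, zero_panel(), alpha = 0.05)
  expect_true(clean$pass)
  expect_lt(clean$p_value, 1e-10)
  # oracle cross-check of the fallback tail
  expect_equal(clean$p_value,
               pbinom(5, 60, 0.5 / 6001, lower.tail = FALSE), tolerance = 1e-12)

  # zero observed support never beats noise
  z <- betabinomial_pon_test(0, 60, zero_panel())
  expect_equal(z$p_value, 1)
  expect_false(z$pass)

  # observation typical of a homogeneous noisy panel: non-significant
  noisy <- structure(list(k = rep(6L, 100), n = rep(60L, 100)), class = "panel_counts")
  typ <- betabinomial_pon_test(6, 60, noisy, alpha = 0.05)
  expect_false(typ$pass)
  expect_gte(typ$p_value, 0.05)

  # recurrent artifact: 40% of panel individuals at rate 0.1
  rec <- structure(list(k = c(rep(6L, 40), rep(0L, 60)), n = rep(60L, 100)),
                   class = "panel_counts")
  art <- betabinomial_pon_test(6, 60, rec, alpha = 0.05)
  expect_false(art$pass)

  # empty panel: policy-controlled
  empty <- structure(list(k = integer(0), n = integer(0)), class = "panel_counts")
  expect_true(betabinomial_pon_test(6, 60, empty)$pass)
  expect_identical(betabinomial_pon_test(6, 60, empty)$note, "no_pon")
  expect_false(betabinomial_pon_test(6, 60, empty, empty_panel_policy = "fail")$pass)
})

test_that("panel p-values are monotone non-increasing in observed support", {
  panels <- list(zero_panel(),
                 structure(list(k = c(rep(0L, 70), rep(5L, 30)), n = rep(60L, 100)),
                           class = "panel_counts"))
  for (panel in panels) {
    p <- vapply(0:20, function(k) betabinomial_pon_test(k, 60, panel)$p_value, numeric(1))
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("joint multi-sample binomial capture dominates single-sample capture", {
  # germline hets across 5 tissues: surviving (falsely somatic) requires the
  # binomial test significant in EVERY sample, which can only be rarer than
  # in any single sample
  set.seed(909)
  for (d in c(20L, 40L, 60L, 100L)) {
    p_by_k <- vapply(0:d, function(k) binomial_germline_test(k, d)$p_value, numeric(1))
    k <- matrix(rbinom(5 * 2000, d, 0.5), nrow = 5)
    sig <- matrix(p_by_k[k + 1] < 0.05, nrow = 5)
    frac_joint <- mean(colSums(sig) == 5)
    frac_single <- mean(sig)
    expect_lte(frac_joint, frac_single)
  }
})
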