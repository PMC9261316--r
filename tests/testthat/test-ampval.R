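amp_site <- function(vafs_by_sample, individuals, depth = 18000L,
                     ref = "A", alt = "T", error = 0) {
  samples <- names(vafs_by_sample)
  rows <- lapply(seq_along(samples), function(i) {
    v <- vafs_by_sample[[i]]
    alt_n <- round(depth * v)
    err_n <- round(depth * error)
    cnt <- c(A = depth - alt_n - 2 * err_n, C = err_n, G = err_n, T = alt_n)
    data.frame(chrom = "1", pos = 100L, ref = ref, alt = alt,
               sample_id = samples[i], individual_id = individuals[i],
               A = cnt["A"], C = cnt["C"], G = cnt["G"], T = cnt["T"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$depth <- out$A + out$C + out$G + out$T
  out$site_key <- paste0("1:100:", ref, ">", alt)
  out
}

test_that("coverage sufficiency uses mean minus one standard deviation", {
  expect_true(coverage_sufficient(18000, rep(18000, 10)))     # sd = 0
  d <- c(rep(18000, 9), 1000)
  expect_false(coverage_sufficient(1000, d))   # 1000 < 16300 - 5375
  expect_true(coverage_sufficient(18000, d))
  expect_true(coverage_sufficient(5, 5))       # single depth: vacuous
})

test_that("sample validation needs allele rank 2 and a background exceedance", {
  # candidate at 8% VAF against ~0.1% background in 8 other-individual samples
  vafs <- c(s1 = 0.08, o1 = 0.001, o2 = 0.0012, o3 = 0.0009, o4 = 0.001,
            o5 = 0.0011, o6 = 0.001, o7 = 0.0008, o8 = 0.001)
  inds <- c("A", paste0("I", 1:8))
  amp <- amp_site(vafs, inds)
  v <- validate_sample(amp, "s1")
  expect_identical(v$status, "validated")
  expect_gt(v$vaf, v$threshold)

  # alt ranked third behind a larger error allele fails rule 1
  amp2 <- amp
  amp2$G[amp2$sample_id == "s1"] <- amp2$T[amp2$sample_id == "s1"] + 50L
  amp2$C[amp2$sample_id == "s1"] <- amp2$T[amp2$sample_id == "s1"] + 40L
  amp2$A[amp2$sample_id == "s1"] <- amp2$depth[amp2$sample_id == "s1"] -
    amp2$T[amp2$sample_id == "s1"] - amp2$G[amp2$sample_id == "s1"] -
    amp2$C[amp2$sample_id == "s1"]
  v2 <- validate_sample(amp2, "s1")
  expect_identical(v2$status, "not_validated")

  # equality with mean + 2 sd is not an exceedance (strict >)
  vafs3 <- c(s1 = 0.002, o1 = 0.001, o2 = 0.003, o3 = 0.001, o4 = 0.003)
  amp3 <- amp_site(vafs3, c("A", "I1", "I2", "I3", "I4"), depth = 10000L)
  bg <- c(0.001, 0.003, 0.001, 0.003)
  expect_equal(validate_sample(amp3, "s1")$threshold,
               mean(bg) + 2 * sd(bg), tolerance = 1e-12)
  # 0.002 < 0.002 + 2*sd -> not validated
  expect_identical(validate_sample(amp3, "s1")$status, "not_validated")
})

test_that("low-coverage samples are flagged before any VAF comparison", {
  vafs <- c(s1 = 0.08, o1 = 0.001, o2 = 0.001, o3 = 0.001)
  amp <- amp_site(vafs, c("A", "I1", "I2", "I3"))
  amp$A[1] <- 200L; amp$T[1] <- 30L; amp$depth[1] <- 230L
  expect_identical(validate_sample(amp, "s1")$status, "low_coverage")
})

test_that("site classification applies the germline VAF reclassification", {
  expect_identical(classify_site(rep("validated", 3), c(0.45, 0.48, 0.52)),
                   "germline_het")
  expect_identical(classify_site(c("validated", rep("not_validated", 4)),
                                 c(0.12, 0, 0, 0, 0)),
                   "somatic_single_tissue")
  expect_identical(classify_site(c(rep("validated", 4), "not_validated"),
                                 c(0.11, 0.02, 0.01, 0.01, 0)),
                   "somatic_multi_tissue")
  expect_identical(classify_site(rep("not_validated", 5), rep(0, 5)),
                   "false_positive")
  # two validated but one below the germline bound stays somatic
  expect_identical(classify_site(c("validated", "validated"), c(0.45, 0.05)),
                   "somatic_multi_tissue")
})

test_that("classification is invariant to tissue order", {
  set.seed(21)
  st <- c("validated", "validated", "not_validated", "validated", "low_coverage")
  vf <- c(0.4, 0.31, 0, 0.6, NA)
  base <- classify_site(st, vf)
  for (i in 1:10) {
    p <- sample(5)
    expect_identical(classify_site(st[p], vf[p]), base)
  }
})

test_that("a planted variant validates in every carrier tissue at depth", {
  scn <- sim_scenario(seed = 5, n_individuals = 4, n_germline = 1, n_somatic = 1,
                      n_artifacts_per_class = 0)
  sim <- simulate_cohort(scn)
  amp <- simulate_amplicon(sim$truth, scn)
  res <- validate_amplicons(amp, sim$truth[, c("site_key", "individual_id")])
  som_key <- sim$truth$site_key[sim$truth$class == "somatic"]
  germ_key <- sim$truth$site_key[sim$truth$class == "germline"]
  expect_identical(res$per_site$class[res$per_site$site_key == som_key],
                   "somatic_multi_tissue")
  expect_identical(res$per_site$class[res$per_site$site_key == germ_key],
                   "germline_het")
  ps <- res$per_sample[res$per_sample$site_key == som_key, ]
  expect_true(all(ps$status == "validated"))
})
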