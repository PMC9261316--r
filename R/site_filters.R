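#' Exact binomial test against germline heterozygosity
#'
#' A germline heterozygous site draws alt reads as Binomial(depth, 0.5); a
#' low-frequency somatic variant does not. The filter therefore requires a
#' SIGNIFICANT two-sided exact binomial test: significance rejects the
#' germline hypothesis and supports somatic origin.
#'
#' @param ad_alt alt-supporting read count.
#' @param depth_used informative depth (ref + alt reads).
#' @param alpha significance level.
#' @return list with \code{p_value}, \code{statistic} (observed alt fraction)
#'   and \code{pass} (p < alpha). Zero depth fails closed with p = NA.
#' @export
binomial_germline_test <- function(ad_alt, depth_used, alpha = 0.05) {
  if (depth_used < 1) return(list(p_value = NA_real_, statistic = NA_real_, pass = FALSE))
  p <- stats::binom.test(ad_alt, depth_used, p = 0.5, alternative = "two.sided")$p.value
  list(p_value = p, statistic = ad_alt / depth_used, pass = p < alpha)
}

#' Exact test of strand-count balance
#'
#' Treats the forward and reverse alt counts as two Poisson rates and applies
#' the classical exact equality-of-rates construction: conditional on the
#' total, the forward count is Binomial(total, 0.5), tested two-sided. True
#' variants are strand-balanced, so the filter requires NON-significance.
#'
#' @param fwd_alt,rev_alt alt read counts per strand.
#' @param alpha significance level.
#' @return list with \code{p_value}, \code{statistic} (forward fraction) and
#'   \code{pass} (p >= alpha). Both counts zero fails closed.
#' @export
poisson_strand_test <- function(fwd_alt, rev_alt, alpha = 0.05) {
  tot <- fwd_alt + rev_alt
  if (tot < 1) return(list(p_value = NA_real_, statistic = NA_real_, pass = FALSE))
  p <- stats::binom.test(fwd_alt, tot, p = 0.5, alternative = "two.sided")$p.value
  list(p_value = p, statistic = fwd_alt / tot, pass = p >= alpha)
}

#' Strand count ratio
#'
#' Larger strand count over the smaller, with a pseudo-count of 1 in the
#' denominator so zero counts stay finite. Passes when strictly below the
#' threshold.
#'
#' @param fwd_alt,rev_alt alt read counts per strand.
#' @param ratio_max strict upper bound.
#' @return list with \code{ratio} and \code{pass}.
#' @export
strand_ratio <- function(fwd_alt, rev_alt, ratio_max = 2) {
  r <- max(fwd_alt, rev_alt) / max(min(fwd_alt, rev_alt), 1)
  list(ratio = r, pass = r < ratio_max)
}

#' Read1/read2 count ratio
#'
#' Same construction as [strand_ratio()] applied to the mate-in-pair counts
#' of the alt allele.
#'
#' @param r1_alt,r2_alt alt read counts by mate.
#' @param ratio_max strict upper bound.
#' @return list with \code{ratio} and \code{pass}.
#' @export
pair_ratio <- function(r1_alt, r2_alt, ratio_max = 4) {
  r <- max(r1_alt, r2_alt) / max(min(r1_alt, r2_alt), 1)
  list(ratio = r, pass = r < ratio_max)
}

#' Position-in-reads bias score
#'
#' Collapsed mapping of paralogous or unresolved sequence leaves the
#' alternative allele clustered at read ends. The score sums four boolean
#' sub-checks of one allele's normalized read positions:
#' \enumerate{
#'   \item median position within \code{median_band};
#'   \item at most \code{end_frac_max} of observations within
#'     \code{end_window} of either read end;
#'   \item at least 2 distinct positions (or exactly one observation);
#'   \item a two-sided Wilcoxon rank-sum test against the other allele's
#'     positions non-significant at \code{ranksum_alpha} (auto-pass when
#'     either allele has fewer than 3 observations).
#' }
#' An unbiased allele scores 4; empty input scores 0.
#'
#' @param positions normalized positions (0-1) of one allele's observations.
#' @param other_positions normalized positions of the other allele.
#' @param median_band inclusive central band for sub-score 1.
#' @param end_window,end_frac_max read-end clustering rule for sub-score 2.
#' @param ranksum_alpha alpha for sub-score 4.
#' @return Integer score 0-4.
#' @export
pir_score <- function(positions, other_positions = numeric(0),
                      median_band = c(0.2, 0.8), end_window = 0.1,
                      end_frac_max = 0.5, ranksum_alpha = 0.05) {
  if (!length(positions)) return(0L)
  s1 <- {
    m <- stats::median(positions)
    m >= median_band[1] && m <= median_band[2]
  }
  near_end <- positions <= end_window | positions >= 1 - end_window
  s2 <- mean(near_end) <= end_frac_max
  s3 <- length(unique(positions)) >= 2 || length(positions) == 1
  s4 <- if (length(positions) < 3 || length(other_positions) < 3) TRUE else {
    p <- suppressWarnings(stats::wilcox.test(positions, other_positions,
                                             alternative = "two.sided", exact = FALSE)$p.value)
    is.na(p) || p >= ranksum_alpha
  }
  as.integer(s1 + s2 + s3 + s4)
}

#' Per-allele clipped-read fraction difference
#'
#' @param clip_frac_ref,clip_frac_alt fractions of clipped reads per allele.
#' @param diff_max strict upper bound on the absolute difference.
#' @return list with \code{difference} and \code{pass}; a missing fraction
#'   (no reads for that allele) fails closed.
#' @export
clip_difference <- function(clip_frac_ref, clip_frac_alt, diff_max = 0.9) {
  if (is.na(clip_frac_ref) || is.na(clip_frac_alt))
    return(list(difference = NA_real_, pass = FALSE))
  d <- abs(clip_frac_alt - clip_frac_ref)
  # strict bound with a guard so floating-point representations of the
  # threshold itself (e.g. |0.95 - 0.05|) count as at the boundary
  list(difference = d, pass = (diff_max - d) > 1e-9)
}

#' Mann-Whitney imbalance test between alleles
#'
#' Two-sided rank-sum comparison of a per-read metric (mapping quality or
#' mismatch count) between ref- and alt-supporting reads. A real variant
#' shows no systematic difference, so the filter requires non-significance.
#' Auto-passes when either allele has fewer than 3 reads (imbalance cannot be
#' assessed); an empty list fails closed.
#'
#' @param values_ref,values_alt per-read values for each allele.
#' @param alpha significance level.
#' @return list with \code{p_value} and \code{pass}.
#' @export
allele_rank_test <- function(values_ref, values_alt, alpha = 0.05) {
  if (!length(values_ref) || !length(values_alt))
    return(list(p_value = NA_real_, pass = FALSE))
  if (length(values_ref) < 3 || length(values_alt) < 3)
    return(list(p_value = NA_real_, pass = TRUE))
  p <- suppressWarnings(stats::wilcox.test(values_ref, values_alt,
                                           alternative = "two.sided", exact = FALSE)$p.value)
  if (is.na(p)) p <- 1
  list(p_value = p, pass = p >= alpha)
}

#' Evaluate the full per-site filter battery
#'
#' Applies every enabled criterion to one sample's evidence at one site and
#' assembles a \code{filter_verdict}: threshold checks (alt depth, VAF, depth
#' range, recount VAF, nearby variants, haplotypes, CNV overlap), ratio
#' checks (strand, pair), the exact tests (germline binomial, strand
#' Poisson), position-in-reads scores for both alleles, clipping difference,
#' the two Mann-Whitney imbalance tests, and (when a panel is supplied) the
#' beta-binomial panel-of-normals test.
#'
#' @param ev a \code{site_evidence} object.
#' @param cfg a \code{filter_config}.
#' @param single_sample logical; use \code{min_alt_depth_single} instead of
#'   \code{min_alt_depth}.
#' @param cnv_overlap logical; TRUE when a CNV call overlaps this site in
#'   this sample.
#' @param panel optional \code{panel_counts} for the site (see
#'   [betabinomial_pon_test()]); omitted panel passes with an annotation.
#' @return An object of class \code{filter_verdict} with a \code{results}
#'   data.frame (filter, pass, statistic, p_value) and \code{overall_pass}.
#' @export
threshold_battery <- function(ev, cfg, single_sample = FALSE,
                              cnv_overlap = FALSE, panel = NULL) {
  res <- list()
  add <- function(name, pass, statistic = NA_real_, p_value = NA_real_) {
    res[[name]] <<- data.frame(filter = name, pass = isTRUE(pass),
                               statistic = as.numeric(statistic),
                               p_value = as.numeric(p_value),
                               stringsAsFactors = FALSE)
  }

  ad_min <- if (single_sample) cfg$min_alt_depth_single else cfg$min_alt_depth
  add("alt_depth", ev$ad_alt >= ad_min, statistic = ev$ad_alt)
  add("vaf", ev$vaf < cfg$vaf_max, statistic = ev$vaf)
  add("depth_range", ev$depth >= cfg$depth_min && ev$depth <= cfg$depth_max,
      statistic = ev$depth)
  add("vaf_recount", ev$vaf_recount < cfg$vaf_recount_max, statistic = ev$vaf_recount)

  sr <- strand_ratio(ev$fwd_alt, ev$rev_alt, cfg$strand_ratio_max)
  add("strand_ratio", sr$pass, statistic = sr$ratio)
  pr <- pair_ratio(ev$r1_alt, ev$r2_alt, cfg$pair_ratio_max)
  add("pair_ratio", pr$pass, statistic = pr$ratio)

  sp <- poisson_strand_test(ev$fwd_alt, ev$rev_alt, cfg$poisson_alpha)
  add("strand_poisson", sp$pass, statistic = sp$statistic, p_value = sp$p_value)

  bt <- binomial_germline_test(ev$ad_alt, ev$ad_ref + ev$ad_alt, cfg$binomial_alpha)
  add("germline_binomial", bt$pass, statistic = bt$statistic, p_value = bt$p_value)

  add("nearby_variants", ev$n_nearby_variants <= cfg$max_nearby_variants,
      statistic = ev$n_nearby_variants)
  add("haplotypes", ev$n_haplotypes < cfg$max_haplotypes, statistic = ev$n_haplotypes)
  if (cfg$require_no_cnv) add("cnv", !isTRUE(cnv_overlap), statistic = as.numeric(cnv_overlap))

  add("pir_ref", pir_score(ev$pir_positions_ref, ev$pir_positions_alt) >= cfg$pir_min_ref,
      statistic = pir_score(ev$pir_positions_ref, ev$pir_positions_alt))
  add("pir_alt", pir_score(ev$pir_positions_alt, ev$pir_positions_ref) >= cfg$pir_min_alt,
      statistic = pir_score(ev$pir_positions_alt, ev$pir_positions_ref))

  cd <- clip_difference(ev$clip_frac_ref, ev$clip_frac_alt, cfg$clip_diff_max)
  add("clip_diff", cd$pass, statistic = cd$difference)

  mq <- allele_rank_test(ev$mq_ref, ev$mq_alt, cfg$mq_alpha)
  add("mq_rank", mq$pass, p_value = mq$p_value)
  mm <- allele_rank_test(ev$mm_ref, ev$mm_alt, cfg$mismatch_alpha)
  add("mismatch_rank", mm$pass, p_value = mm$p_value)

  if (!is.null(panel)) {
    pt <- betabinomial_pon_test(ev$ad_alt, ev$ad_ref + ev$ad_alt, panel, cfg$pon_alpha)
    add("pon", pt$pass, p_value = pt$p_value)
  }

  results <- do.call(rbind, res)
  rownames(results) <- NULL
  structure(list(
    site = ev$site,
    sample_id = ev$sample_id,
    results = results,
    overall_pass = all(results$pass)
  ), class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat(sprintf("<filter_verdict> %s sample=%s overall=%s\n",
              x$site$site_key[1], x$sample_id,
              if (x$overall_pass) "PASS" else
                paste0("FAIL[", paste(x$results$filter[!x$results$pass], collapse = ";"), "]")))
  invisible(x)
}

#' Failing-filter names from a verdict
#' @param verdict a \code{filter_verdict}.
#' @return Character vector of failing criterion names (empty when PASS).
#' @export
failing_filters <- function(verdict) {
  verdict$results$filter[!verdict$results$pass]
}
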