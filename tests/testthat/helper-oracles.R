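# Independent oracles and fixture builders used across the suite.

# Exact two-sided binomial p-value by brute-force tail enumeration: sum the
# probability of every outcome no more likely than the observed one.
two_sided_binom_oracle <- function(k, n, p = 0.5) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Beta-binomial upper tail by numerical integration over the latent rate:
# P(X >= k) = E_p[ P(Bin(n, p) >= k) ], p ~ Beta(a, b).
betabinom_tail_oracle <- function(k, n, a, b) {
  if (k <= 0) return(1)
  f <- function(p) stats::dbeta(p, a, b) * stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

# Balanced clean observation frame: alternating strands/mates, evenly spread
# read positions, constant qualities — passes every orthogonal filter.
make_clean_obs <- function(n_ref, n_alt, read_length = 100L, chrom = "1",
                           pos = 5000L, sample_id = "s1",
                           alt_positions = NULL, alt_strands = NULL,
                           mq = 60L, bq = 35L) {
  mk <- function(n, allele) {
    if (n == 0) return(NULL)
    p <- floor((seq_len(n) - 0.5) / n * (read_length - 1))
    s <- rep_len(c("+", "-"), n)
    if (allele == "alt" && !is.null(alt_positions)) p <- alt_positions
    if (allele == "alt" && !is.null(alt_strands)) s <- alt_strands
    data.frame(chrom = chrom, pos = pos, sample_id = sample_id, allele = allele,
               strand = s, mate = rep_len(c("R1", "R2"), n),
               pos_in_read = p, read_length = read_length,
               mapping_quality = mq, n_mismatches = 0L, is_clipped = 0L,
               base_quality = bq, stringsAsFactors = FALSE)
  }
  rbind(mk(n_ref, "ref"), mk(n_alt, "alt"))
}

one_site <- function(chrom = "1", pos = 5000L, ref = "A", alt = "T",
                     sample_id = "s1", individual_id = "ind1") {
  candidate_sites(chrom, pos, ref, alt, sample_id, individual_id)
}

# Minimal verdict stub for cohort-level logic tests.
stub_verdict <- function(pass_by_filter) {
  res <- data.frame(filter = names(pass_by_filter),
                    pass = unname(unlist(pass_by_filter)),
                    statistic = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  structure(list(site = NULL, sample_id = NA_character_, results = res,
                 overall_pass = all(res$pass)), class = "filter_verdict")
}

# An all-zero panel and a noisy panel for PON tests.
zero_panel <- function(n_ind = 100, depth = 60) {
  structure(list(k = rep(0L, n_ind), n = rep(as.integer(depth), n_ind)),
            class = "panel_counts")
}
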