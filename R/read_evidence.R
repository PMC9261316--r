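#' Normalized position of a variant base within its read
#'
#' Offset from the 5' end of the read as sequenced divided by the maximal
#' offset, so 0 is the first sequenced base and 1 the last. Reads of length 1
#' map to 0. Measuring on the read as sequenced keeps end-clustering from
#' collapsed paralogs visible on both strands.
#'
#' @param pos_in_read 0-based offset(s) of the variant base.
#' @param read_length read length(s).
#' @return Numeric vector in [0, 1].
#' @export
normalized_position <- function(pos_in_read, read_length) {
  stopifnot(all(pos_in_read >= 0), all(pos_in_read < read_length))
  ifelse(read_length <= 1L, 0, pos_in_read / (read_length - 1))
}

#' Count other variant positions within one read length
#'
#' @param site_pos 1-based position of the candidate site.
#' @param other_positions positions of other candidate/heterozygous variants
#'   on the same chromosome (the site itself is excluded if present).
#' @param read_length distance bound; positions with
#'   \code{|p - site_pos| <= read_length} are counted.
#' @return Integer count.
#' @export
count_nearby_variants <- function(site_pos, other_positions, read_length) {
  other_positions <- other_positions[other_positions != site_pos]
  sum(abs(other_positions - site_pos) <= read_length)
}

#' Count local haplotypes from read-level phase strings
#'
#' Each read spanning the candidate site and all of its phase sites
#' contributes an allele string (e.g. \code{"R,A"}). The haplotype count is
#' the number of distinct strings supported by at least \code{min_support}
#' reads; the support threshold guards against single sequencing errors
#' creating phantom haplotypes. With no phase sites the strings are the
#' site's own alleles, so a site with both ref and alt reads yields 2.
#'
#' @param hap_strings character vector of allele strings, one per spanning
#'   read; \code{NA} entries (reads not spanning all positions) are dropped.
#' @param min_support minimum reads per haplotype (default 2).
#' @return Integer haplotype count.
#' @export
count_haplotypes <- function(hap_strings, min_support = 2L) {
  hap_strings <- hap_strings[!is.na(hap_strings) & nzchar(hap_strings)]
  if (!length(hap_strings)) return(0L)
  tab <- table(hap_strings)
  sum(tab >= min_support)
}

#' Collect per-site read evidence
#'
#' Aggregates the read observations overlapping one candidate site in one
#' sample into the feature set the filter battery consumes: allele depths,
#' strand and mate counts, VAF and quality-filtered recount VAF, per-allele
#' normalized position lists, clipping fractions, mapping-quality and
#' mismatch lists, nearby-variant count and local haplotype count.
#'
#' Every observation contributes to \code{depth}; \code{other}-allele reads
#' are counted in depth only. Observations below \code{min_base_quality} or
#' \code{min_mapping_quality} still count toward the raw allele depths but
#' are excluded from the recount VAF.
#'
#' @param site one-row candidate data.frame (see [candidate_sites()]).
#' @param observations read-observation data.frame for this site and sample
#'   (see [read_evidence_table()] for the schema).
#' @param nearby_positions positions of other candidate/het variants on the
#'   same chromosome.
#' @param read_length modal read length of the library, used for the
#'   nearby-variant window.
#' @param min_base_quality,min_mapping_quality recount thresholds.
#' @return An object of class \code{site_evidence}.
#' @export
collect_evidence <- function(site, observations, nearby_positions = integer(0),
                             read_length = 100L, min_base_quality = 20L,
                             min_mapping_quality = 20L) {
  obs <- observations
  if (is.null(obs) || nrow(obs) == 0) {
    obs <- data.frame(allele = character(0), strand = character(0),
                      mate = character(0), pos_in_read = integer(0),
                      read_length = integer(0), mapping_quality = integer(0),
                      n_mismatches = integer(0), is_clipped = integer(0),
                      base_quality = integer(0), sample_id = character(0),
                      stringsAsFactors = FALSE)
  }
  depth <- nrow(obs)
  is_ref <- obs$allele == "ref"
  is_alt <- obs$allele == "alt"

  ad_ref <- sum(is_ref); ad_alt <- sum(is_alt)
  fwd_alt <- sum(is_alt & obs$strand == "+")
  rev_alt <- sum(is_alt & obs$strand == "-")
  fwd_ref <- sum(is_ref & obs$strand == "+")
  rev_ref <- sum(is_ref & obs$strand == "-")
  r1_alt <- sum(is_alt & obs$mate == "R1")
  r2_alt <- sum(is_alt & obs$mate == "R2")

  vaf <- if (ad_ref + ad_alt > 0) ad_alt / (ad_ref + ad_alt) else 0
  hq <- obs$base_quality >= min_base_quality & obs$mapping_quality >= min_mapping_quality
  ad_ref_q <- sum(is_ref & hq); ad_alt_q <- sum(is_alt & hq)
  vaf_recount <- if (ad_ref_q + ad_alt_q > 0) ad_alt_q / (ad_ref_q + ad_alt_q) else 0

  npos <- function(idx) {
    if (!any(idx)) return(numeric(0))
    normalized_position(obs$pos_in_read[idx], obs$read_length[idx])
  }
  clip_frac <- function(idx) if (any(idx)) mean(obs$is_clipped[idx] != 0) else NA_real_

  hap_strings <- if ("hap_string" %in% names(obs)) obs$hap_string else obs$allele
  n_hap <- count_haplotypes(hap_strings)

  structure(list(
    site = site,
    sample_id = if (nrow(obs)) obs$sample_id[1] else site$sample_id[1],
    depth = depth,
    ad_ref = ad_ref, ad_alt = ad_alt,
    fwd_alt = fwd_alt, rev_alt = rev_alt,
    fwd_ref = fwd_ref, rev_ref = rev_ref,
    r1_alt = r1_alt, r2_alt = r2_alt,
    vaf = vaf, vaf_recount = vaf_recount,
    pir_positions_ref = npos(is_ref),
    pir_positions_alt = npos(is_alt),
    clip_frac_ref = clip_frac(is_ref),
    clip_frac_alt = clip_frac(is_alt),
    mq_ref = obs$mapping_quality[is_ref],
    mq_alt = obs$mapping_quality[is_alt],
    mm_ref = obs$n_mismatches[is_ref],
    mm_alt = obs$n_mismatches[is_alt],
    n_nearby_variants = count_nearby_variants(site$pos[1], nearby_positions, read_length),
    n_haplotypes = n_hap
  ), class = "site_evidence")
}

#' @export
print.site_evidence <- function(x, ...) {
  cat(sprintf("<site_evidence> %s sample=%s depth=%d ad=%d/%d vaf=%.3f\n",
              x$site$site_key[1], x$sample_id, x$depth, x$ad_ref, x$ad_alt, x$vaf))
  invisible(x)
}
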