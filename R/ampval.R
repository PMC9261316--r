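#' Coverage sufficiency for an amplicon sample
#'
#' A sample's depth at an amplicon is sufficient when it is not lower than
#' the mean minus one standard deviation of all samples' depths at that
#' amplicon. With fewer than two depths the criterion is vacuously met.
#'
#' @param depth the sample's depth.
#' @param all_depths depths of all samples at this amplicon.
#' @return Logical.
#' @export
coverage_sufficient <- function(depth, all_depths) {
  if (length(all_depths) < 2) return(TRUE)
  depth >= mean(all_depths) - stats::sd(all_depths)
}

#' Validate one sample at one amplicon site
#'
#' A candidate variant is validated in a sample when (1) the alt allele is
#' the second most common allele in that sample (ties with the second rank
#' count as satisfying the rule) and (2) its VAF exceeds the mean plus
#' \code{z_mult} standard deviations of the alt VAFs in all
#' coverage-sufficient samples from OTHER individuals (strict inequality).
#' Samples failing the coverage rule are \code{low_coverage}.
#'
#' @param amp amplicon count data.frame for ONE site (rows = samples;
#'   columns \code{sample_id}, \code{individual_id}, \code{ref}, \code{alt},
#'   \code{A}, \code{C}, \code{G}, \code{T}, \code{depth}).
#' @param sample id of the sample to evaluate.
#' @param z_mult background multiplier (default 2).
#' @return list with \code{status} ("validated", "not_validated",
#'   "low_coverage" or "no_background"), \code{vaf} and \code{threshold}.
#' @export
validate_sample <- function(amp, sample, z_mult = 2) {
  row <- amp[amp$sample_id == sample, , drop = FALSE]
  stopifnot(nrow(row) == 1)
  alt <- row$alt[1]
  if (!coverage_sufficient(row$depth[1], amp$depth))
    return(list(status = "low_coverage", vaf = NA_real_, threshold = NA_real_))

  counts <- unlist(row[1, c("A", "C", "G", "T")])
  vaf <- if (row$depth[1] > 0) counts[[alt]] / row$depth[1] else 0
  # rule 1: alt within the top-2 alleles (ties at rank 2 accepted; a het
  # drifting above 50% VAF still satisfies the rule)
  rank2_count <- sort(counts, decreasing = TRUE)[2]
  is_second <- counts[[alt]] >= rank2_count

  bg_rows <- amp[amp$individual_id != row$individual_id[1], , drop = FALSE]
  bg_rows <- bg_rows[vapply(seq_len(nrow(bg_rows)), function(i)
    coverage_sufficient(bg_rows$depth[i], amp$depth), logical(1)), , drop = FALSE]
  if (nrow(bg_rows) == 0)
    return(list(status = "no_background", vaf = vaf, threshold = NA_real_))
  bg_vaf <- ifelse(bg_rows$depth > 0, bg_rows[[alt]] / bg_rows$depth, 0)
  thr <- mean(bg_vaf) + z_mult * stats::sd(bg_vaf)
  if (is.na(thr)) thr <- mean(bg_vaf)  # single background sample: sd undefined

  status <- if (is_second && vaf > thr) "validated" else "not_validated"
  list(status = status, vaf = vaf, threshold = thr)
}

#' Classify an amplicon site from per-sample validation statuses
#'
#' Sites validated in two or more tissues with VAF above
#' \code{germline_vaf_min} in ALL validated tissues are reclassified as
#' germline heterozygous; otherwise the class reflects the number of
#' validated tissues. The classification is invariant to tissue order.
#'
#' @param statuses character vector of per-sample statuses (from
#'   [validate_sample()]) for the candidate individual's samples.
#' @param vafs matching VAFs.
#' @param germline_vaf_min germline reclassification bound (default 0.30).
#' @return One of \code{"germline_het"}, \code{"somatic_multi_tissue"},
#'   \code{"somatic_single_tissue"}, \code{"false_positive"}.
#' @export
classify_site <- function(statuses, vafs, germline_vaf_min = 0.30) {
  ok <- statuses == "validated"
  n_val <- sum(ok)
  if (n_val >= 2 && all(vafs[ok] > germline_vaf_min)) return("germline_het")
  if (n_val >= 2) return("somatic_multi_tissue")
  if (n_val == 1) return("somatic_single_tissue")
  "false_positive"
}

#' Run amplicon validation over a full count table
#'
#' Applies [validate_sample()] to every sample of the candidate individual
#' at every site and [classify_site()] to the per-sample outcomes.
#'
#' @param amp_table amplicon table (see [read_amplicon_table()]) covering
#'   all samples; the candidate individual is taken per site from
#'   \code{candidate_individual} when present, else must be supplied.
#' @param candidates optional candidate data.frame restricting site to
#'   individual assignment (columns \code{site_key}, \code{individual_id}).
#' @param z_mult background multiplier.
#' @param germline_vaf_min germline reclassification bound.
#' @return list with \code{per_sample} (long data.frame: site_key, sample,
#'   status, vaf) and \code{per_site} (site_key, individual, class,
#'   n_validated).
#' @export
validate_amplicons <- function(amp_table, candidates = NULL, z_mult = 2,
                               germline_vaf_min = 0.30) {
  per_sample <- list(); per_site <- list()
  for (key in unique(amp_table$site_key)) {
    amp <- amp_table[amp_table$site_key == key, , drop = FALSE]
    cand_ind <- if (!is.null(candidates)) {
      unique(candidates$individual_id[candidates$site_key == key])
    } else if ("candidate_individual" %in% names(amp)) {
      unique(amp$candidate_individual)
    } else {
      stop("candidate individual unknown for site ", key)
    }
    for (ind in cand_ind) {
      rows <- amp$sample_id[amp$individual_id == ind]
      out <- lapply(rows, function(s) validate_sample(amp, s, z_mult))
      statuses <- vapply(out, `[[`, character(1), "status")
      vafs <- vapply(out, `[[`, numeric(1), "vaf")
      per_sample[[length(per_sample) + 1L]] <- data.frame(
        site_key = key, individual_id = ind, sample_id = rows,
        status = statuses, vaf = vafs, stringsAsFactors = FALSE)
      per_site[[length(per_site) + 1L]] <- data.frame(
        site_key = key, individual_id = ind,
        class = classify_site(statuses, vafs, germline_vaf_min),
        n_validated = sum(statuses == "validated"), stringsAsFactors = FALSE)
    }
  }
  list(per_sample = do.call(rbind, per_sample), per_site = do.call(rbind, per_site))
}
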