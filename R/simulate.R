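#' Define a simulation scenario
#'
#' The scenario encodes the study design the filters assume: ten individuals
#' with five tissues each (one blood, four brain) sequenced to ~60X with
#' 100 bp reads, an external allele-count panel, and ultra-deep (18,000X)
#' amplicon resequencing. Site classes cover germline heterozygotes
#' (population SNPs, so they recur in the external panel and cohort),
#' true somatic variants (blood VAF 11.5%, brain 0.7% by default, the
#' blood/brain mosaicism pattern), and five artifact classes:
#' \code{strand_biased}, \code{end_clustered} (collapsed paralog),
#' \code{pon_recurrent}, \code{near_indel} and \code{high_depth_cnv}.
#'
#' @param seed RNG seed; a fixed seed makes every simulated table identical.
#' @param n_individuals,samples_per_individual cohort shape.
#' @param depth_mean exome depth (Poisson mean).
#' @param depth_amplicon amplicon depth.
#' @param read_length library read length (bp).
#' @param error_rate per-base substitution error rate.
#' @param pon_individuals external panel size.
#' @param n_germline,n_somatic,n_artifacts_per_class site counts per class.
#' @param somatic_vaf_blood,somatic_vaf_brain somatic allele frequencies by
#'   tissue role in the exome data.
#' @param min_plant_support minimum alt reads drawn for a planted somatic in
#'   its carrier (blood) sample. Plants are drawn within the method's
#'   sensitivity envelope: with the strand-ratio bound strict at 2, a
#'   detectable single-sample variant needs at least 4 balanced supporting
#'   reads, so the blood draw is a truncated binomial at this floor.
#' @param amplicon_brain_vaf somatic brain VAF at amplicon depth (detectable
#'   only ultra-deep).
#' @param germline_af_range population allele-frequency range for germline
#'   SNP sites.
#' @param pon_recurrent_support,pon_recurrent_rate artifact recurrence:
#'   fraction of panel individuals showing the artifact and its allele rate.
#' @return A list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(seed = 1L, n_individuals = 10L, samples_per_individual = 5L,
                         depth_mean = 60L, depth_amplicon = 18000L, read_length = 100L,
                         error_rate = 1e-3, pon_individuals = 100L,
                         n_germline = 80L, n_somatic = 5L, n_artifacts_per_class = 3L,
                         somatic_vaf_blood = 0.115, somatic_vaf_brain = 0.007,
                         min_plant_support = 4L, amplicon_brain_vaf = 0.015,
                         germline_af_range = c(0.1, 0.4),
                         pon_recurrent_support = 0.4, pon_recurrent_rate = 0.1) {
  scn <- as.list(environment())
  stopifnot(scn$error_rate >= 0, scn$error_rate <= 1,
            scn$somatic_vaf_blood <= 1, scn$seed == as.integer(scn$seed))
  structure(scn, class = "sim_scenario")
}

.artifact_classes <- c("strand_biased", "end_clustered", "pon_recurrent",
                       "near_indel", "high_depth_cnv")

# Which filter is designed to reject each artifact class
#' Map artifact classes to their designated rejecting filter
#' @return Named character vector class -> filter/mask name.
#' @export
artifact_filter_map <- function() {
  c(strand_biased = "strand_ratio", end_clustered = "pir_alt",
    pon_recurrent = "pon", near_indel = "near_indel",
    high_depth_cnv = "depth_range")
}

.tissues <- c("bl", "cb", "cx", "sn", "st")

.sample_ids <- function(ind, k) paste0("ind", ind, "_", .tissues[seq_len(k)])

# Balanced clean read observations: strands and mates alternate, positions
# are spread on an even grid, qualities constant. This idealization makes a
# clean variant pass every orthogonal filter so that each artifact class is
# rejected by its designated filter only (biases are then injected on top).
.make_obs <- function(n_ref, n_alt, read_length, class = "clean") {
  mk <- function(n, allele) {
    if (n == 0) return(NULL)
    pos <- floor((seq_len(n) - 0.5) / n * (read_length - 1))
    strand <- rep_len(c("+", "-"), n)
    if (allele == "alt" && class == "strand_biased") {
      n_fwd <- ceiling(0.9 * n)
      strand <- c(rep("+", n_fwd), rep("-", n - n_fwd))
    }
    if (allele == "alt" && class == "end_clustered") {
      pos <- sample.int(max(1L, floor(0.08 * (read_length - 1))), n, replace = TRUE) - 1L
    }
    data.frame(allele = allele, strand = strand,
               mate = rep_len(c("R1", "R2"), n),
               pos_in_read = pos, read_length = read_length,
               mapping_quality = 60L, n_mismatches = 0L,
               is_clipped = 0L, base_quality = 35L,
               stringsAsFactors = FALSE)
  }
  rbind(mk(n_ref, "ref"), mk(n_alt, "alt"))
}

#' Simulate a multi-tissue cohort with planted truth
#'
#' Generates, under the scenario's fixed seed: a reference sequence, a
#' candidate table, per-read evidence for every sample of each site's owner
#' individual, region masks (with indels planted next to \code{near_indel}
#' sites and CNV calls over \code{high_depth_cnv} sites), a genome-wide
#' depth table (overdispersed background, so the central-75\% depth band
#' spans the normal coverage range), an external panel allele-count table,
#' a cohort alt-support summary for cross-individual recurrence, and a truth
#' table recording each site's class and designated rejecting filter.
#'
#' Germline sites draw alt counts as Binomial(depth, 0.5) in every sample of
#' their individual and segregate in the panel and cohort at their population
#' frequency. Somatic sites use the tissue VAFs of the scenario. Artifact
#' sites carry their class-specific bias.
#'
#' @param scn a [sim_scenario()].
#' @return A list with elements \code{truth}, \code{candidates},
#'   \code{evidence}, \code{masks}, \code{pon}, \code{depth_table},
#'   \code{cohort_support}, \code{reference} and \code{scenario}.
#' @export
simulate_cohort <- function(scn) {
  set.seed(scn$seed)
  classes <- c(rep("germline", scn$n_germline), rep("somatic", scn$n_somatic),
               rep(.artifact_classes, each = scn$n_artifacts_per_class))
  n_sites <- length(classes)
  classes <- sample(classes)  # interleave classes along the chromosome
  spacing <- 2L * scn$read_length + 1000L
  pos <- 1000L + spacing * seq_len(n_sites)
  chrom_len <- max(pos) + 2000L

  bases <- c("A", "C", "G", "T")
  ref_seq <- paste(sample(bases, chrom_len, replace = TRUE), collapse = "")
  reference <- Biostrings::DNAStringSet(ref_seq)
  names(reference) <- "1"

  ref <- substring(ref_seq, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  owner <- rep_len(seq_len(scn$n_individuals), n_sites)[sample.int(n_sites)]
  owner_id <- paste0("ind", owner)

  truth <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                      individual_id = owner_id, class = classes,
                      stringsAsFactors = FALSE)
  truth$site_key <- site_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  fmap <- artifact_filter_map()
  truth$designated_filter <- ifelse(truth$class %in% names(fmap),
                                    fmap[truth$class], NA_character_)
  truth$germline_af <- ifelse(truth$class == "germline",
                              stats::runif(n_sites, scn$germline_af_range[1],
                                           scn$germline_af_range[2]), NA_real_)

  evidence <- vector("list", n_sites)
  cand <- vector("list", n_sites)
  indel_positions <- list()
  cnv_calls <- list()
  support <- vector("list", n_sites)

  err3 <- scn$error_rate / 3
  for (i in seq_len(n_sites)) {
    cls <- classes[i]
    smp <- .sample_ids(owner[i], scn$samples_per_individual)
    site_rows <- list()
    for (s_idx in seq_along(smp)) {
      is_blood <- s_idx == 1L
      depth <- if (cls == "high_depth_cnv") {
        max(120L, stats::rpois(1, 2.5 * scn$depth_mean))
      } else {
        max(20L, stats::rpois(1, scn$depth_mean))
      }
      vaf <- switch(cls,
        germline = 0.5,
        somatic = if (is_blood) scn$somatic_vaf_blood else scn$somatic_vaf_brain,
        strand_biased = 0.12,
        end_clustered = 0.12,
        pon_recurrent = scn$pon_recurrent_rate,
        near_indel = if (is_blood) 0.12 else 0,
        high_depth_cnv = 0.35)
      ad_alt <- stats::rbinom(1, depth, vaf)
      # planted somatics are drawn within the method's sensitivity envelope:
      # the lax caller only emits sites with minimal read support, so the
      # blood (carrier) draw is a truncated binomial at min_plant_support
      if (cls == "somatic" && is_blood) {
        while (ad_alt < scn$min_plant_support) ad_alt <- stats::rbinom(1, depth, vaf)
      }
      if (cls %in% c("strand_biased", "end_clustered") && ad_alt < 4) ad_alt <- 4L
      obs <- .make_obs(depth - ad_alt, ad_alt, scn$read_length, class = cls)
      obs <- cbind(data.frame(chrom = "1", pos = pos[i], sample_id = smp[s_idx],
                              stringsAsFactors = FALSE), obs)
      obs$hap_string <- obs$allele
      site_rows[[s_idx]] <- obs
      if (ad_alt > 0) {
        cand[[length(cand) + 1L]] <- data.frame(
          chrom = "1", pos = pos[i], ref = ref[i], alt = alt[i],
          sample_id = smp[s_idx], individual_id = owner_id[i],
          caller_tag = "sim", ad_ref = depth - ad_alt, ad_alt = ad_alt,
          stringsAsFactors = FALSE)
      }
    }
    evidence[[i]] <- do.call(rbind, site_rows)

    if (cls == "near_indel") {
      indel_positions[[length(indel_positions) + 1L]] <-
        data.frame(chrom = "1", pos = pos[i] + 3L)
    }
    if (cls == "high_depth_cnv") {
      for (s in smp) {
        gr <- GenomicRanges::GRanges("1", IRanges::IRanges(pos[i] - 500L, pos[i] + 500L))
        cnv_calls[[s]] <- if (is.null(cnv_calls[[s]])) gr else c(cnv_calls[[s]], gr)
      }
    }

    # cross-individual alt support (max alt reads in any sample of each
    # OTHER individual) for the cohort recurrence filter
    # support reflects true variant presence in other individuals (germline
    # SNPs segregate at their population frequency; recurrent artifacts
    # recur); sporadic single-read errors are below the support summary
    others <- setdiff(seq_len(scn$n_individuals), owner[i])
    n_alt_other <- vapply(others, function(o) {
      switch(cls,
        germline = {
          af <- truth$germline_af[i]
          if (stats::runif(1) < 2 * af * (1 - af))
            stats::rbinom(1, scn$depth_mean, 0.5) else 0L
        },
        pon_recurrent = {
          if (stats::runif(1) < scn$pon_recurrent_support)
            stats::rbinom(1, scn$depth_mean, scn$pon_recurrent_rate) else 0L
        },
        0L)
    }, integer(1))
    support[[i]] <- data.frame(site_key = truth$site_key[i],
                               individual_id = paste0("ind", others),
                               n_alt_reads = n_alt_other,
                               stringsAsFactors = FALSE)
  }

  evidence <- do.call(rbind, evidence)
  candidates0 <- do.call(rbind, cand)
  candidates <- candidate_sites(candidates0$chrom, candidates0$pos, candidates0$ref,
                                candidates0$alt, candidates0$sample_id,
                                candidates0$individual_id, candidates0$caller_tag)
  candidates$ad_ref <- candidates0$ad_ref
  candidates$ad_alt <- candidates0$ad_alt

  # panel of normals: all candidate positions, one row per panel individual
  pon <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    n_p <- pmax(10L, stats::rpois(scn$pon_individuals, scn$depth_mean))
    k <- switch(classes[i],
      germline = {
        af <- truth$germline_af[i]
        carrier <- stats::runif(scn$pon_individuals) < 2 * af * (1 - af)
        ifelse(carrier, stats::rbinom(scn$pon_individuals, n_p, 0.5),
               stats::rbinom(scn$pon_individuals, n_p, err3))
      },
      pon_recurrent = {
        hit <- stats::runif(scn$pon_individuals) < scn$pon_recurrent_support
        ifelse(hit, stats::rbinom(scn$pon_individuals, n_p, scn$pon_recurrent_rate),
               stats::rbinom(scn$pon_individuals, n_p, err3))
      },
      stats::rbinom(scn$pon_individuals, n_p, err3))
    out <- data.frame(individual = paste0("pon", seq_len(scn$pon_individuals)),
                      chrom = "1", pos = pos[i], ref = ref[i],
                      A = 0L, C = 0L, G = 0L, T = 0L, stringsAsFactors = FALSE)
    out[[ref[i]]] <- n_p - k
    out[[alt[i]]] <- out[[alt[i]]] + k
    out
  }))
  class(pon) <- c("pon_table", class(pon))

  # genome-wide depth table: overdispersed capture background plus the
  # candidate positions at their simulated pooled depths
  avail <- setdiff(seq(100L, chrom_len - 100L, by = 50L), pos)
  bg_pos <- sort(sample(avail, min(2000L, length(avail))))
  depth_table <- rbind(
    data.frame(chrom = "1", pos = bg_pos,
               depth = stats::rnbinom(length(bg_pos), size = 3, mu = scn$depth_mean)),
    data.frame(chrom = "1", pos = pos,
               depth = as.integer(round(tapply(rep(1, nrow(evidence)), evidence$pos,
                                               length)[as.character(pos)] /
                                          scn$samples_per_individual)))
  )

  masks <- mask_set(
    targets = GenomicRanges::GRanges("1", IRanges::IRanges(1L, chrom_len)),
    indel_positions = if (length(indel_positions)) do.call(rbind, indel_positions) else NULL,
    depth_exclusion = depth_exclusion_from_cohort(depth_table, keep_fraction = 0.75),
    cnv_calls = cnv_calls
  )

  list(truth = truth, candidates = candidates, evidence = evidence,
       masks = masks, pon = pon, depth_table = depth_table,
       cohort_support = do.call(rbind, support), reference = reference,
       scenario = scn)
}

#' Simulate amplicon ultra-deep allele counts
#'
#' Multinomial base counts at amplicon depth for every sample of every
#' individual at each truth site: somatic sites carry their tissue VAFs in
#' the owner individual (blood high, brain low but detectable at depth),
#' germline sites ~48\% VAF in all owner tissues, all other samples pure
#' noise with errors spread uniformly over the non-ref bases.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param scn the [sim_scenario()].
#' @param seed optional seed overriding the scenario seed.
#' @return An amplicon count data.frame (see [read_amplicon_table()]).
#' @export
simulate_amplicon <- function(truth, scn, seed = scn$seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    cls <- truth$class[i]
    for (ind in seq_len(scn$n_individuals)) {
      ind_id <- paste0("ind", ind)
      smp <- .sample_ids(ind, scn$samples_per_individual)
      for (s_idx in seq_along(smp)) {
        vaf <- 0
        if (ind_id == truth$individual_id[i]) {
          vaf <- switch(cls,
            somatic = if (s_idx == 1L) scn$somatic_vaf_blood else scn$amplicon_brain_vaf,
            germline = 0.48,
            0)
        }
        p <- rep(scn$error_rate / 3, 4); names(p) <- bases
        p[truth$alt[i]] <- vaf + scn$error_rate / 3
        p[truth$ref[i]] <- 1 - sum(p[setdiff(bases, truth$ref[i])])
        cnt <- stats::rmultinom(1, scn$depth_amplicon, p)[, 1]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = truth$chrom[i], pos = truth$pos[i], ref = truth$ref[i],
          alt = truth$alt[i], sample_id = smp[s_idx], individual_id = ind_id,
          A = cnt["A"], C = cnt["C"], G = cnt["G"], T = cnt["T"],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$depth <- out$A + out$C + out$G + out$T
  out$site_key <- site_key(out$chrom, out$pos, out$ref, out$alt)
  out
}
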