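#' Filter a multi-tissue cohort of candidate sites
#'
#' The core pipeline: for every candidate site and owner individual it
#' (1) checks callability against the mask set, (2) collects read evidence
#' for each of the individual's samples, (3) evaluates the filter battery
#' twice per sample (single-sample and combined alt-depth thresholds),
#' (4) resolves the configured single/combined/both mode, and (5) applies
#' the cross-individual cohort recurrence filter. A site survives when it is
#' callable, the mode decision passes and no more than the tolerated number
#' of other individuals show alt support.
#'
#' @param candidates candidate-site data.frame (see [candidate_sites()]).
#' @param evidence per-read evidence data.frame (see
#'   [read_evidence_table()]) covering every sample of each site's owner
#'   individual; sample to individual assignment is taken from
#'   \code{sample_map} or inferred as \code{"<individual>_<tissue>"}.
#' @param masks a [mask_set()].
#' @param pon a \code{pon_table} or NULL (panel test then auto-passes with a
#'   "no_pon" note).
#' @param cfg a [filter_config()].
#' @param cohort_support data.frame (\code{site_key}, \code{individual_id},
#'   \code{n_alt_reads}) summarising alt support in other individuals; NULL
#'   disables the recurrence filter.
#' @param sample_map optional named vector sample id -> individual id for
#'   evidence samples absent from \code{candidates}.
#' @return list of class \code{cohort_run}: \code{decisions} (one row per
#'   site x individual), \code{verdicts} (long per-sample per-filter table),
#'   \code{manifest} (telescoping stage counts and the criterion co-failure
#'   matrix).
#' @export
filter_cohort <- function(candidates, evidence, masks, pon, cfg,
                          cohort_support = NULL, sample_map = NULL) {
  if (nrow(candidates) == 0) {
    decisions <- data.frame(site_key = character(0), chrom = character(0),
                            pos = integer(0), ref = character(0), alt = character(0),
                            individual_id = character(0), callable = logical(0),
                            mask_reasons = character(0), n_samples = integer(0),
                            single_pass = logical(0), combined_pass = logical(0),
                            recurrence_support = integer(0), recurrence_pass = logical(0),
                            mode = character(0), final_pass = logical(0))
    return(structure(list(decisions = decisions, verdicts = NULL,
                          manifest = build_manifest(decisions, NULL, cfg)),
                     class = "cohort_run"))
  }
  sites <- unique(candidates[, c("site_key", "chrom", "pos", "ref", "alt")])
  if (is.null(sample_map)) {
    ids <- unique(c(candidates$sample_id, evidence$sample_id))
    # default convention: sample ids are "<individual>_<tissue>"
    sample_map <- stats::setNames(sub("_[^_]+$", "", ids), ids)
    sample_map[candidates$sample_id] <- candidates$individual_id
  }

  units <- unique(candidates[, c("site_key", "individual_id")])
  call_tab <- is_callable(sites$chrom, sites$pos, masks)
  call_tab$site_key <- sites$site_key
  all_pos <- sites$pos[order(sites$chrom, sites$pos)]

  decisions <- list(); verdicts <- list()
  for (u in seq_len(nrow(units))) {
    key <- units$site_key[u]; ind <- units$individual_id[u]
    site <- sites[sites$site_key == key, , drop = FALSE]
    cl <- call_tab[call_tab$site_key == key, , drop = FALSE]

    ev_site <- evidence[evidence$chrom == site$chrom & evidence$pos == site$pos, , drop = FALSE]
    smp <- sort(unique(ev_site$sample_id[sample_map[ev_site$sample_id] == ind]))
    nearby <- setdiff(sites$pos[sites$chrom == site$chrom], site$pos)
    panel <- if (!is.null(pon)) panel_counts(pon, site$chrom, site$pos, site$alt) else NULL

    v_single <- list(); v_combined <- list()
    for (s in smp) {
      obs <- ev_site[ev_site$sample_id == s, , drop = FALSE]
      ev <- collect_evidence(site, obs, nearby_positions = nearby,
                             read_length = cfg$read_length,
                             min_base_quality = cfg$recount_min_bq,
                             min_mapping_quality = cfg$recount_min_mq)
      ev$sample_id <- s
      cnv <- cnv_overlap(site$chrom, site$pos, masks, s)
      v_single[[s]] <- threshold_battery(ev, cfg, single_sample = TRUE,
                                         cnv_overlap = cnv, panel = panel)
      v_combined[[s]] <- threshold_battery(ev, cfg, single_sample = FALSE,
                                           cnv_overlap = cnv, panel = panel)
      for (leg in c("single", "combined")) {
        vv <- if (leg == "single") v_single[[s]] else v_combined[[s]]
        verdicts[[length(verdicts) + 1L]] <- cbind(
          data.frame(site_key = key, individual_id = ind, sample_id = s,
                     leg = leg, stringsAsFactors = FALSE), vv$results)
      }
    }

    dec <- resolve_mode(v_single, v_combined, cfg)
    rec <- if (!is.null(cohort_support)) {
      sup <- cohort_support[cohort_support$site_key == key &
                              cohort_support$individual_id != ind, , drop = FALSE]
      panel_recurrence(sup$n_alt_reads >= cfg$panel_support_min_reads,
                       cfg$max_panel_recurrence)
    } else list(n_support = 0L, pass = TRUE)

    decisions[[u]] <- data.frame(
      site_key = key, chrom = site$chrom, pos = site$pos, ref = site$ref,
      alt = site$alt, individual_id = ind,
      callable = cl$callable, mask_reasons = cl$reasons,
      n_samples = length(smp),
      single_pass = dec$single_pass, combined_pass = dec$combined_pass,
      recurrence_support = rec$n_support, recurrence_pass = rec$pass,
      mode = dec$mode_used,
      final_pass = cl$callable && dec$final_pass && rec$pass,
      stringsAsFactors = FALSE)
  }
  decisions <- do.call(rbind, decisions)
  verdicts <- if (length(verdicts)) do.call(rbind, verdicts) else NULL

  manifest <- build_manifest(decisions, verdicts, cfg)
  structure(list(decisions = decisions, verdicts = verdicts, manifest = manifest),
            class = "cohort_run")
}

#' Build the run manifest
#'
#' Telescoping stage counts (candidate units in = non-callable removed +
#' evaluated; evaluated = failed + survivors), per-criterion failure counts
#' over the combined-leg sample verdicts, and the criterion co-failure
#' matrix (for every pair of criteria, the number of sample-level
#' evaluations failing both).
#'
#' @param decisions,verdicts tables from [filter_cohort()].
#' @param cfg the configuration used.
#' @return list of class \code{run_manifest}.
#' @export
build_manifest <- function(decisions, verdicts, cfg) {
  n_units <- nrow(decisions)
  n_noncallable <- sum(!decisions$callable)
  n_evaluated <- n_units - n_noncallable
  n_survivors <- sum(decisions$final_pass)
  fail_counts <- NULL; cofail <- NULL
  if (!is.null(verdicts)) {
    vc <- verdicts[verdicts$leg == "combined", , drop = FALSE]
    filters <- unique(vc$filter)
    fail_counts <- vapply(filters, function(f)
      sum(!vc$pass[vc$filter == f]), integer(1))
    unit <- paste(vc$site_key, vc$sample_id)
    fm <- matrix(FALSE, nrow = length(unique(unit)), ncol = length(filters),
                 dimnames = list(unique(unit), filters))
    fm[cbind(match(unit, rownames(fm)), match(vc$filter, filters))] <- !vc$pass
    cofail <- t(fm) %*% fm
  }
  structure(list(
    config = render_config(cfg),
    counts = list(candidate_units = n_units, non_callable = n_noncallable,
                  evaluated = n_evaluated,
                  failed = n_evaluated - n_survivors, survivors = n_survivors),
    filter_failure_counts = as.list(fail_counts),
    cofailure_matrix = cofail
  ), class = "run_manifest")
}

#' Write the per-site FILTER-annotated VCF
#'
#' One record per site; FILTER is \code{PASS} when any individual's decision
#' passed, else the semicolon-joined union of failing criteria (mask reasons
#' and per-filter names from the combined leg, plus \code{recurrence} and
#' mode failure markers).
#'
#' @param run a \code{cohort_run}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_filtered_vcf <- function(run, path) {
  dec <- run$decisions
  keys <- unique(dec$site_key)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MODE,Number=1,Type=String,Description=\"Filtering mode provenance\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                 collapse = "\t"))
  lines <- hdr
  for (k in keys) {
    d <- dec[dec$site_key == k, , drop = FALSE]
    if (any(d$final_pass)) {
      filt <- "PASS"
      prov <- paste0("MODE=", paste(unique(c(
        if (any(d$single_pass & d$final_pass)) "SINGLE_PASS",
        if (any(d$combined_pass & d$final_pass)) "COMBINED_PASS")), collapse = ","))
    } else {
      reasons <- character(0)
      if (any(!d$callable)) reasons <- c(reasons, strsplit(d$mask_reasons[!d$callable], ";")[[1]])
      if (!is.null(run$verdicts)) {
        vv <- run$verdicts[run$verdicts$site_key == k & run$verdicts$leg == "combined", ]
        bad <- unique(vv$filter[!vv$pass])
        reasons <- c(reasons, bad)
      }
      if (any(!d$recurrence_pass)) reasons <- c(reasons, "recurrence")
      filt <- paste(unique(reasons), collapse = ";")
      if (!nzchar(filt)) filt <- "mode_fail"
      prov <- "MODE=NONE"
    }
    lines <- c(lines, paste(c(d$chrom[1], d$pos[1], ".", d$ref[1], d$alt[1], ".",
                              filt, prov), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the filtering workflow over files or objects
#'
#' File-level wrapper around [filter_cohort()]: accepts paths (VCF
#' candidates, evidence TSV, PON TSV) or the equivalent in-memory objects,
#' executes annotate -> mask -> filter -> cohort decision, and optionally
#' writes the FILTER-annotated VCF, the long verdict TSV and a JSON
#' manifest into \code{out_dir}.
#'
#' @param candidates path to a VCF or a candidate data.frame.
#' @param evidence path to an evidence TSV or a data.frame.
#' @param masks a [mask_set()].
#' @param pon path to a PON TSV, a \code{pon_table}, or NULL.
#' @param cfg a [filter_config()] or a parameter string for [parse_config()].
#' @param cohort_support optional recurrence summary (see [filter_cohort()]).
#' @param sample_map optional sample -> individual map.
#' @param out_dir optional output directory.
#' @return The \code{cohort_run}, invisibly when writing files.
#' @export
run_filter <- function(candidates, evidence, masks, pon = NULL, cfg = filter_config(),
                       cohort_support = NULL, sample_map = NULL, out_dir = NULL) {
  if (is.character(cfg)) cfg <- parse_config(cfg)
  if (is.character(candidates)) candidates <- read_candidates(candidates, sample_map)
  if (is.character(evidence)) evidence <- read_evidence_table(evidence)
  if (is.character(pon)) pon <- read_pon_table(pon)
  run <- filter_cohort(candidates, evidence, masks, pon, cfg,
                       cohort_support = cohort_support, sample_map = sample_map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_filtered_vcf(run, file.path(out_dir, "filtered.vcf"))
    utils::write.table(run$verdicts, file.path(out_dir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    man <- run$manifest
    man$cofailure_matrix <- as.data.frame(as.matrix(man$cofailure_matrix))
    jsonlite::write_json(unclass(man), file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(run))
  }
  run
}

#' Run amplicon validation over files or objects
#'
#' @param amplicons path to an amplicon count TSV or a data.frame.
#' @param candidates candidate data.frame assigning sites to individuals
#'   (columns \code{site_key}, \code{individual_id}).
#' @param z_mult,germline_vaf_min see [validate_sample()] and
#'   [classify_site()].
#' @param out_dir optional output directory for the per-sample and per-site
#'   TSVs.
#' @return The [validate_amplicons()] result.
#' @export
run_validate <- function(amplicons, candidates, z_mult = 2, germline_vaf_min = 0.30,
                         out_dir = NULL) {
  if (is.character(amplicons)) amplicons <- read_amplicon_table(amplicons)
  if (is.null(candidates$site_key) || is.null(candidates$individual_id))
    stop("candidates must provide site_key and individual_id")
  res <- validate_amplicons(amplicons, candidates, z_mult, germline_vaf_min)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$per_sample, file.path(out_dir, "validation_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$per_site, file.path(out_dir, "validation_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Run the mutational-spectrum analysis
#'
#' Classifies validated substitutions into the 96 trinucleotide-context
#' categories and correlates the spectrum with a signature matrix.
#'
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA.
#' @param signatures a signature matrix or path to its TSV (see
#'   [read_signature_matrix()]).
#' @param r_min correlation reporting bound.
#' @param out_dir optional output directory (spectrum TSV + correlations TSV).
#' @return list with \code{spectrum} and \code{correlations}.
#' @export
run_spectrum <- function(variants, reference, signatures, r_min = 0.3, out_dir = NULL) {
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("I/O error: missing reference FASTA '", reference, "'")
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (is.character(signatures)) signatures <- read_signature_matrix(signatures)
  spec <- count_spectrum(variants$chrom, variants$pos, variants$ref, variants$alt,
                         reference)
  corr <- correlate_signatures(spec, signatures, r_min)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(context = names(spec), count = as.integer(spec)),
                       file.path(out_dir, "spectrum.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(corr, file.path(out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(spectrum = spec, correlations = corr)
}
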