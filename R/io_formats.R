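#' Candidate site table
#'
#' Candidate sSNVs are represented as a plain data.frame with one row per
#' (site, sample) pair and columns \code{chrom}, \code{pos} (1-based),
#' \code{ref}, \code{alt} (single bases), \code{sample_id},
#' \code{individual_id} and \code{caller_tag}. A stable site key
#' (\code{"chrom:pos:ref>alt"}) is added as column \code{site_key}.
#'
#' @param chrom,pos,ref,alt,sample_id,individual_id,caller_tag vectors of
#'   equal length (recycled where length 1).
#' @return A data.frame of candidate sites.
#' @export
candidate_sites <- function(chrom, pos, ref, alt, sample_id,
                            individual_id = sample_id, caller_tag = "unknown") {
  if (length(chrom) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), sample_id = character(0),
                      individual_id = character(0), caller_tag = character(0),
                      site_key = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
                   sample_id = as.character(sample_id),
                   individual_id = as.character(individual_id),
                   caller_tag = as.character(caller_tag),
                   stringsAsFactors = FALSE)
  bad <- !(df$ref %in% c("A", "C", "G", "T")) | !(df$alt %in% c("A", "C", "G", "T")) |
    df$ref == df$alt | df$pos < 1L
  if (any(bad)) stop("invalid candidate site(s): ref/alt must be distinct single bases, pos >= 1")
  df$site_key <- site_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

site_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

#' Read candidate SNVs from a VCF
#'
#' One candidate is emitted per sample with a non-reference genotype or a
#' nonzero alt allele depth (AD field). Multi-allelic records are split into
#' biallelic candidates and each alt evaluated independently; indel alleles
#' are skipped and counted.
#'
#' @param vcf_path path to a VCF 4.x file (plain or bgzipped).
#' @param sample_map named character vector mapping sample id to individual
#'   id; samples absent from the map keep their own id as individual.
#' @param caller_tag label recorded as the call origin.
#' @return A candidate-site data.frame (see [candidate_sites()]) with an
#'   attribute \code{n_indels_skipped}.
#' @export
read_candidates <- function(vcf_path, sample_map = NULL, caller_tag = "vcf") {
  if (!file.exists(vcf_path)) stop("I/O error: cannot read VCF '", vcf_path, "'")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    out <- candidate_sites(character(0), integer(0), character(0), character(0), character(0))
    attr(out, "n_indels_skipped") <- 0L
    return(out)
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)  # keeps matrix shape at n = 1
  gt <- if (ncol(v@gt) > 1) vcfR::extract.gt(v, element = "GT") else NULL
  ad <- if (ncol(v@gt) > 1) vcfR::extract.gt(v, element = "AD") else NULL
  samples <- if (!is.null(gt)) colnames(gt) else character(0)

  rows <- list()
  n_indels <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      if (nchar(ref) != 1 || nchar(alt) != 1 || !alt %in% c("A", "C", "G", "T")) {
        n_indels <- n_indels + 1L
        next
      }
      for (s in samples) {
        g <- gt[i, s]
        adv <- ad[i, s]
        called <- FALSE
        if (!is.na(g) && grepl(as.character(ai), g, fixed = TRUE)) called <- TRUE
        if (!called && !is.na(adv)) {
          counts <- suppressWarnings(as.integer(strsplit(adv, ",", fixed = TRUE)[[1]]))
          if (length(counts) > ai && !is.na(counts[ai + 1]) && counts[ai + 1] > 0) called <- TRUE
        }
        if (called) {
          ind <- if (!is.null(sample_map) && s %in% names(sample_map)) sample_map[[s]] else s
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = ref, alt = alt,
            sample_id = s, individual_id = ind, caller_tag = caller_tag,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) {
    df <- do.call(rbind, rows)
    candidate_sites(df$chrom, df$pos, df$ref, df$alt, df$sample_id,
                    df$individual_id, df$caller_tag)
  } else {
    candidate_sites(character(0), integer(0), character(0), character(0), character(0))
  }
  attr(out, "n_indels_skipped") <- n_indels
  out
}

#' Write a candidate table as a minimal VCF 4.2
#'
#' Emits one record per site with GT and AD genotype fields per sample
#' (alt depth from \code{ad_alt}/\code{ad_ref} columns when present, else a
#' placeholder het). Used by the simulator and round-trip tests; plain text.
#'
#' @param candidates candidate-site data.frame; optional columns
#'   \code{ad_ref}, \code{ad_alt} per row.
#' @param path output path.
#' @param all_samples character vector of sample columns to emit (defaults to
#'   the samples present).
#' @return \code{path}, invisibly.
#' @export
write_candidate_vcf <- function(candidates, path, all_samples = NULL) {
  if (is.null(all_samples)) all_samples <- sort(unique(candidates$sample_id))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", all_samples), collapse = "\t"))
  lines <- hdr
  if (nrow(candidates)) {
    keys <- unique(candidates$site_key)
    for (k in keys) {
      sub <- candidates[candidates$site_key == k, , drop = FALSE]
      gt <- vapply(all_samples, function(s) {
        row <- sub[sub$sample_id == s, , drop = FALSE]
        if (nrow(row) == 0) return("0/0:30,0")
        adr <- if ("ad_ref" %in% names(row)) row$ad_ref[1] else 30L
        ada <- if ("ad_alt" %in% names(row)) row$ad_alt[1] else 30L
        paste0("0/1:", adr, ",", ada)
      }, character(1))
      lines <- c(lines, paste(c(sub$chrom[1], sub$pos[1], ".", sub$ref[1], sub$alt[1],
                                ".", ".", ".", "GT:AD", gt), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED mask into an interval set
#'
#' BED input is 0-based half-open; intervals are converted to the 1-based
#' inclusive convention used throughout the package, so a BED line
#' \code{chr 99 200} covers 1-based positions 100..200. Records with
#' start >= end are rejected with a warning.
#'
#' @param bed_path path to a BED file (3+ columns).
#' @return A [GenomicRanges::GRanges] object.
#' @export
read_bed_mask <- function(bed_path) {
  if (!file.exists(bed_path)) stop("I/O error: cannot read BED '", bed_path, "'")
  raw <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric", rep("NULL", 20))[1:3],
                           col.names = c("chrom", "start", "end"),
                           fill = TRUE, comment.char = "#")
  if (nrow(raw) == 0) return(GenomicRanges::GRanges())
  bad <- raw$start >= raw$end
  if (any(bad)) {
    warning(sum(bad), " BED record(s) with start >= end rejected")
    raw <- raw[!bad, , drop = FALSE]
  }
  GenomicRanges::GRanges(raw$chrom, IRanges::IRanges(start = raw$start + 1L, end = raw$end))
}

#' Test 1-based positions for overlap with an interval set
#'
#' @param gr a GRanges interval set (1-based, as from [read_bed_mask()]).
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @return Logical vector.
#' @export
positions_overlap <- function(gr, chrom, pos) {
  if (length(gr) == 0 || length(pos) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(as.character(chrom), IRanges::IRanges(pos, pos))
  suppressWarnings(GenomicRanges::countOverlaps(q, gr) > 0)
}

#' Read a panel-of-normals allele-count table
#'
#' The schema is a long-format TSV with columns \code{individual},
#' \code{chrom}, \code{pos}, \code{ref}, \code{A}, \code{C}, \code{G},
#' \code{T}: one row per panel individual per site, giving the base counts
#' observed in that individual at that position.
#'
#' @param path path to the TSV.
#' @return A data.frame of class \code{pon_table}.
#' @export
read_pon_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read PON table '", path, "'")
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("individual", "chrom", "pos", "ref", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    stop("parse error: PON table must have columns ", paste(need, collapse = ", "))
  for (b in c("A", "C", "G", "T")) {
    v <- suppressWarnings(as.integer(df[[b]]))
    if (anyNA(v)) stop("parse error: non-integer count in PON column ", b)
    if (any(v < 0)) stop("parse error: negative count in PON column ", b)
    df[[b]] <- v
  }
  df$pos <- as.integer(df$pos)
  class(df) <- c("pon_table", class(df))
  df
}

#' Extract panel counts for one site and alt allele
#'
#' @param pon a \code{pon_table}.
#' @param chrom,pos site coordinates.
#' @param alt alt allele whose counts to extract.
#' @return A list of class \code{panel_counts} with integer vectors \code{k}
#'   (alt counts) and \code{n} (total depths), one entry per panel individual;
#'   both empty when the site is absent from the table.
#' @export
panel_counts <- function(pon, chrom, pos, alt) {
  sub <- pon[pon$chrom == chrom & pon$pos == pos, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(structure(list(k = integer(0), n = integer(0)), class = "panel_counts"))
  }
  n <- sub$A + sub$C + sub$G + sub$T
  k <- sub[[alt]]
  structure(list(k = as.integer(k), n = as.integer(n)), class = "panel_counts")
}

#' Read an amplicon allele-count table
#'
#' Long-format TSV with columns \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}, \code{sample_id}, \code{individual_id}, \code{A}, \code{C},
#' \code{G}, \code{T}: per-sample base counts from ultra-deep amplicon
#' resequencing of each candidate site.
#'
#' @param path path to the TSV.
#' @return A data.frame with a \code{depth} column (sum of the four counts)
#'   and \code{site_key}.
#' @export
read_amplicon_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read amplicon table '", path, "'")
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "sample_id", "individual_id", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    stop("parse error: amplicon table must have columns ", paste(need, collapse = ", "))
  for (b in c("A", "C", "G", "T")) {
    if (any(df[[b]] < 0)) stop("parse error: negative amplicon count")
  }
  df$pos <- as.integer(df$pos)
  df$depth <- df$A + df$C + df$G + df$T
  df$site_key <- site_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' Read a signature matrix
#'
#' TSV with a \code{context} column holding the 96 category labels (e.g.
#' \code{"A[C>T]G"}) and one numeric column per signature; each signature
#' column must sum to 1 (tolerance 1e-6) and rows are reordered to the
#' canonical category ordering (see [sbs96_categories()]).
#'
#' @param path path to the TSV.
#' @return A numeric matrix, 96 rows (contexts) by signatures.
#' @export
read_signature_matrix <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read signature matrix '", path, "'")
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"context" %in% names(df)) stop("parse error: signature matrix needs a 'context' column")
  cats <- sbs96_categories()
  if (!setequal(df$context, cats))
    stop("parse error: signature matrix must cover exactly the 96 context categories")
  m <- as.matrix(df[match(cats, df$context), setdiff(names(df), "context"), drop = FALSE])
  rownames(m) <- cats
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-6))
    stop("parse error: signature column(s) do not sum to 1: ",
         paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "))
  m
}

#' Read a per-read evidence table
#'
#' The evidence table is the package's alignment-free read representation:
#' one row per read observation at a candidate site, with columns
#' \code{chrom}, \code{pos}, \code{sample_id}, \code{allele} (\code{ref},
#' \code{alt} or \code{other}), \code{strand} (\code{+}/\code{-}),
#' \code{mate} (\code{R1}/\code{R2}), \code{pos_in_read} (0-based offset from
#' the 5' end of the read as sequenced), \code{read_length},
#' \code{mapping_quality}, \code{n_mismatches}, \code{is_clipped} (0/1),
#' \code{base_quality} and optionally \code{hap_string} (comma-joined alleles
#' over the site and its phase sites for reads spanning all of them).
#'
#' @param path path to the TSV.
#' @return A data.frame of read observations.
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read evidence table '", path, "'")
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "sample_id", "allele", "strand", "mate", "pos_in_read",
            "read_length", "mapping_quality", "n_mismatches", "is_clipped", "base_quality")
  if (!all(need %in% names(df)))
    stop("parse error: evidence table must have columns ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df
}

#' Write a per-read evidence table
#' @param evidence data.frame of read observations.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_evidence_table <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
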