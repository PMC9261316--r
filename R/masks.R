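#' Assemble a mask set
#'
#' Bundles the region masks defining the non-callable set: capture targets
#' (callable sites must be on-target), the genome strict/accessibility mask,
#' segmental duplications, low-mappability regions, homopolymer runs,
#' indel positions (sites within \code{indel_pad} bp are removed), a
#' cohort-level depth exclusion set, and per-sample CNV calls (consumed by
#' the per-sample filter battery rather than the global mask).
#'
#' @param targets,strict_mask,segdups,low_mappability,homopolymers GRanges
#'   interval sets (1-based; see [read_bed_mask()]); NULL disables a mask.
#' @param indel_positions data.frame with \code{chrom}, \code{pos} columns.
#' @param depth_exclusion data.frame with \code{chrom}, \code{pos} columns
#'   (see [depth_exclusion_from_cohort()]).
#' @param cnv_calls named list (by sample id) of GRanges.
#' @return An object of class \code{mask_set}.
#' @export
mask_set <- function(targets = NULL, strict_mask = NULL, segdups = NULL,
                     low_mappability = NULL, homopolymers = NULL,
                     indel_positions = NULL, depth_exclusion = NULL,
                     cnv_calls = list()) {
  structure(list(targets = targets, strict_mask = strict_mask, segdups = segdups,
                 low_mappability = low_mappability, homopolymers = homopolymers,
                 indel_positions = indel_positions, depth_exclusion = depth_exclusion,
                 cnv_calls = cnv_calls), class = "mask_set")
}

#' Site callability against the mask set
#'
#' A site is callable iff it is on-target (when a target set is provided) and
#' overlaps none of: strict mask, segmental duplications, low mappability,
#' homopolymers, depth exclusion, nor lies within \code{indel_pad} bp of an
#' indel. Every violated mask is reported as a reason.
#'
#' @param chrom,pos site coordinates (vectors of equal length).
#' @param masks a \code{mask_set}.
#' @param indel_pad indel proximity bound in bp (default 5; a site exactly
#'   \code{indel_pad} bp away is removed, one base further is kept).
#' @return A data.frame with columns \code{chrom}, \code{pos},
#'   \code{callable} and \code{reasons} (semicolon-joined; "" when callable).
#' @export
is_callable <- function(chrom, pos, masks, indel_pad = 5L) {
  n <- length(pos)
  reasons <- vector("list", n)
  hit <- function(gr) positions_overlap(gr, chrom, pos)
  addr <- function(flag, label) {
    for (i in which(flag)) reasons[[i]] <<- c(reasons[[i]], label)
  }
  if (!is.null(masks$targets)) addr(!hit(masks$targets), "off_target")
  if (!is.null(masks$strict_mask)) addr(hit(masks$strict_mask), "strict_mask")
  if (!is.null(masks$segdups)) addr(hit(masks$segdups), "segdup")
  if (!is.null(masks$low_mappability)) addr(hit(masks$low_mappability), "low_mappability")
  if (!is.null(masks$homopolymers)) addr(hit(masks$homopolymers), "homopolymer")
  if (!is.null(masks$depth_exclusion) && nrow(masks$depth_exclusion)) {
    key <- paste(masks$depth_exclusion$chrom, masks$depth_exclusion$pos)
    addr(paste(chrom, pos) %in% key, "depth_exclusion")
  }
  if (!is.null(masks$indel_positions) && nrow(masks$indel_positions)) {
    near <- vapply(seq_len(n), function(i) {
      ip <- masks$indel_positions
      any(ip$chrom == chrom[i] & abs(ip$pos - pos[i]) <= indel_pad)
    }, logical(1))
    addr(near, "near_indel")
  }
  data.frame(chrom = chrom, pos = pos,
             callable = lengths(reasons) == 0,
             reasons = vapply(reasons, function(r) paste(r, collapse = ";"), character(1)),
             stringsAsFactors = FALSE)
}

#' CNV overlap flag for one sample
#'
#' @param chrom,pos site coordinates.
#' @param masks a \code{mask_set} with per-sample \code{cnv_calls}.
#' @param sample_id sample whose CNV calls to query.
#' @return Logical vector.
#' @export
cnv_overlap <- function(chrom, pos, masks, sample_id) {
  gr <- masks$cnv_calls[[sample_id]]
  if (is.null(gr)) return(rep(FALSE, length(pos)))
  positions_overlap(gr, chrom, pos)
}

#' Depth-based exclusion set from the cohort depth distribution
#'
#' Positions with pooled depth in the extreme tails of the empirical
#' distribution are excluded, keeping the central \code{keep_fraction}
#' (symmetric tails of (1 - keep_fraction)/2 each). Cutoffs use type-7
#' quantiles with strict inequalities, so tied uniform depths exclude
#' nothing and \code{keep_fraction = 1} is empty.
#'
#' @param depth_table data.frame with columns \code{chrom}, \code{pos},
#'   \code{depth} (pooled or per-sample-summed depth per position).
#' @param keep_fraction central fraction of the distribution to keep.
#' @return data.frame (\code{chrom}, \code{pos}) of excluded positions.
#' @export
depth_exclusion_from_cohort <- function(depth_table, keep_fraction = 0.75) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  empty <- data.frame(chrom = character(0), pos = integer(0))
  if (is.null(depth_table) || nrow(depth_table) == 0 || keep_fraction == 1) return(empty)
  tail_p <- (1 - keep_fraction) / 2
  q <- stats::quantile(depth_table$depth, c(tail_p, 1 - tail_p), names = FALSE)
  out <- depth_table$depth < q[1] | depth_table$depth > q[2]
  depth_table[out, c("chrom", "pos"), drop = FALSE]
}
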