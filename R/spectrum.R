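#' The 96 trinucleotide-context substitution categories
#'
#' Conventional ordering: six pyrimidine-centered substitution blocks
#' (C>A, C>G, C>T, T>A, T>C, T>G), within each the 16 flanking contexts in
#' alphabetical order of 5' then 3' base. Labels have the form
#' \code{"A[C>T]G"}.
#'
#' @return Character vector of length 96.
#' @export
sbs96_categories <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p5, p3)
      paste0(p5, "[", s, "]", p3))))
  }))
}

.revcomp <- function(x) chartr("ACGT", "TGCA", sapply(strsplit(x, ""), function(b)
  paste(rev(b), collapse = "")))

#' Classify a substitution into its trinucleotide-context category
#'
#' Looks up the flanking bases in the reference and returns the
#' pyrimidine-centered category label: substitutions from a purine reference
#' base are reverse-complemented (variant and context) before labelling, so
#' both strand representations of a mutation map to the same category.
#'
#' @param chrom,pos,ref,alt the substitution (vectors accepted).
#' @param reference a [Biostrings::DNAStringSet] (names = chromosomes).
#' @return Character vector of category labels; \code{NA} (with a warning)
#'   for variants whose context contains an ambiguous base. A mismatch
#'   between \code{ref} and the reference sequence is an error.
#' @export
classify_context <- function(chrom, pos, ref, alt, reference) {
  n <- length(pos)
  out <- character(n)
  for (i in seq_len(n)) {
    seqs <- reference[[chrom[i]]]
    if (pos[i] < 2 || pos[i] > length(seqs) - 1)
      stop("position ", pos[i], " lacks flanking context on ", chrom[i])
    tri <- toupper(as.character(Biostrings::subseq(seqs, pos[i] - 1, pos[i] + 1)))
    if (substr(tri, 2, 2) != toupper(ref[i]))
      stop("ref allele ", ref[i], " does not match reference base ",
           substr(tri, 2, 2), " at ", chrom[i], ":", pos[i])
    if (grepl("[^ACGT]", tri)) {
      warning("ambiguous base in context at ", chrom[i], ":", pos[i], "; variant skipped")
      out[i] <- NA_character_
      next
    }
    r <- toupper(ref[i]); a <- toupper(alt[i])
    if (r %in% c("A", "G")) {
      tri <- .revcomp(tri)
      r <- chartr("ACGT", "TGCA", r)
      a <- chartr("ACGT", "TGCA", a)
    }
    out[i] <- paste0(substr(tri, 1, 1), "[", r, ">", a, "]", substr(tri, 3, 3))
  }
  out
}

#' Count a set of substitutions into a 96-category spectrum
#'
#' @param chrom,pos,ref,alt vectors describing the substitutions.
#' @param reference a [Biostrings::DNAStringSet].
#' @return Named integer vector over [sbs96_categories()] with attribute
#'   \code{n_skipped} (ambiguous-context variants).
#' @export
count_spectrum <- function(chrom, pos, ref, alt, reference) {
  cats <- sbs96_categories()
  labels <- classify_context(chrom, pos, ref, alt, reference)
  skipped <- sum(is.na(labels))
  counts <- table(factor(labels[!is.na(labels)], levels = cats))
  out <- as.integer(counts)
  names(out) <- cats
  attr(out, "n_skipped") <- skipped
  out
}

#' Correlate a mutational spectrum with signature vectors
#'
#' Pearson correlation between the spectrum (normalized to proportions;
#' Pearson is location/scale invariant so counts give identical r) and each
#' signature column, reporting signatures with r above \code{r_min} sorted
#' by decreasing r.
#'
#' @param spectrum 96-element count (or proportion) vector in the canonical
#'   category order.
#' @param signatures matrix from [read_signature_matrix()].
#' @param r_min reporting bound (default 0.3).
#' @return data.frame with columns \code{signature} and \code{r} (all
#'   signatures as attribute \code{all_r}). A zero-variance spectrum (empty
#'   or constant) is an error.
#' @export
correlate_signatures <- function(spectrum, signatures, r_min = 0.3) {
  stopifnot(length(spectrum) == 96, nrow(signatures) == 96)
  if (sum(spectrum) == 0 || stats::var(as.numeric(spectrum)) == 0)
    stop("spectrum has zero variance; correlation undefined")
  prop <- as.numeric(spectrum) / sum(spectrum)
  # a constant (zero-variance) signature column has no defined correlation:
  # it gets NA and is never reported
  r <- apply(signatures, 2, function(sig)
    suppressWarnings(stats::cor(prop, sig)))
  keep <- which(r > r_min)
  out <- data.frame(signature = names(r)[keep], r = unname(r[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_r") <- r
  out
}

#' Bar plot of a 96-category spectrum
#'
#' Base-graphics rendering with one colour block per substitution type,
#' mirroring the conventional signature-plot layout.
#'
#' @param spectrum 96-element vector in canonical order.
#' @param main plot title.
#' @return Invisibly, the input.
#' @export
plot_spectrum <- function(spectrum, main = "Mutational spectrum") {
  cats <- sbs96_categories()
  cols <- rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63", "#EBC6C4"),
              each = 16)
  graphics::barplot(as.numeric(spectrum), col = cols, border = NA,
                    names.arg = rep("", 96), main = main, ylab = "Count")
  graphics::legend("topright", legend = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"),
                   fill = unique(cols), bty = "n", cex = 0.8)
  invisible(spectrum)
}
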