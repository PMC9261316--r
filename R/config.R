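#' Filter configuration
#'
#' A \code{filter_config} holds every threshold used by the per-site filter
#' battery and the cohort-level decision logic. The defaults correspond to an
#' exome-style design: five tissues per individual at ~60X, paired-end 100 bp
#' reads, combined-or-single filtering with four of five tissues required per
#' filter.
#'
#' Flags understood by [parse_config()] (one per field):
#' \describe{
#'   \item{-c}{\code{combined_mode}: SINGLE, COMBINED or BOTH}
#'   \item{-ns}{\code{n_samples_per_ind}: samples required to pass each filter
#'     in combined mode}
#'   \item{-ad}{\code{min_alt_depth}: minimum alt-supporting reads (combined)}
#'   \item{-adss}{\code{min_alt_depth_single}: minimum alt reads, single-sample
#'     mode}
#'   \item{-vaf}{\code{vaf_max}: variant allele frequency upper bound (strict)}
#'   \item{-dp1 / -dp2}{\code{depth_min} / \code{depth_max}: inclusive depth
#'     range}
#'   \item{-sr}{\code{strand_ratio_max}: strand count ratio upper bound
#'     (strict)}
#'   \item{-pr}{\code{pair_ratio_max}: read1/read2 count ratio upper bound
#'     (strict)}
#'   \item{-sp}{\code{poisson_alpha}: alpha for the exact strand Poisson test
#'     (non-significance required)}
#'   \item{-b}{\code{binomial_alpha}: alpha for the germline binomial test
#'     (significance required)}
#'   \item{-nrl}{\code{max_nearby_variants}: maximum other variants within one
#'     read length}
#'   \item{-hap}{\code{max_haplotypes}: local haplotype count must be strictly
#'     below this}
#'   \item{-cnv}{\code{require_no_cnv}: \code{NO} demands absence of a CNV
#'     call overlapping the site in that sample; \code{IGNORE} disables the
#'     filter}
#'   \item{-pir}{\code{pir_min_ref,pir_min_alt}: comma pair of minimum
#'     position-in-reads scores (0-4)}
#'   \item{-vafq}{\code{vaf_recount_max}: VAF recomputed from quality-filtered
#'     read counts, upper bound (strict)}
#'   \item{-clip}{\code{clip_diff_max}: absolute difference in per-allele
#'     clipped-read fractions, upper bound (strict)}
#'   \item{-mq}{\code{mq_alpha}: alpha for the Mann-Whitney mapping-quality
#'     imbalance test (non-significance required)}
#'   \item{-mm}{\code{mismatch_alpha}: alpha for the Mann-Whitney per-read
#'     mismatch imbalance test (non-significance required)}
#'   \item{-pon}{\code{pon_alpha}: alpha for the beta-binomial panel-of-normals
#'     test (significance required)}
#' }
#'
#' @param ... named fields overriding the defaults (field names, not flags).
#' @return An object of class \code{filter_config} (a named list).
#' @seealso [parse_config()], [render_config()]
#' @export
#' @examples
#' cfg <- filter_config(depth_min = 10)
#' cfg$depth_min
filter_config <- function(...) {
  cfg <- list(
    combined_mode       = "BOTH",
    n_samples_per_ind   = 4L,
    min_alt_depth       = 2L,
    min_alt_depth_single = 3L,
    vaf_max             = 0.5,
    depth_min           = 20L,
    depth_max           = 100L,
    strand_ratio_max    = 2,
    pair_ratio_max      = 4,
    poisson_alpha       = 0.05,
    binomial_alpha      = 0.05,
    max_nearby_variants = 4L,
    max_haplotypes      = 4L,
    require_no_cnv      = TRUE,
    pir_min_ref         = 4L,
    pir_min_alt         = 4L,
    vaf_recount_max     = 0.4,
    clip_diff_max       = 0.9,
    mq_alpha            = 0.05,
    mismatch_alpha      = 0.05,
    pon_alpha           = 0.05,
    # auxiliary knobs, not part of the flag string
    read_length         = 100L,
    recount_min_bq      = 20L,
    recount_min_mq      = 20L,
    max_panel_recurrence = 0L,
    panel_support_min_reads = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown filter_config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "filter_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$combined_mode %in% c("SINGLE", "COMBINED", "BOTH"),
    cfg$vaf_max >= 0, cfg$vaf_max <= 1,
    cfg$vaf_recount_max >= 0, cfg$vaf_recount_max <= 1,
    cfg$depth_min < cfg$depth_max,
    cfg$pir_min_ref >= 0, cfg$pir_min_ref <= 4,
    cfg$pir_min_alt >= 0, cfg$pir_min_alt <= 4
  )
  for (a in c("poisson_alpha", "binomial_alpha", "mq_alpha", "mismatch_alpha", "pon_alpha")) {
    if (!(cfg[[a]] > 0 && cfg[[a]] < 1)) stop("alpha '", a, "' must be in (0,1)")
  }
  for (i in c("n_samples_per_ind", "min_alt_depth", "min_alt_depth_single",
              "max_nearby_variants", "max_haplotypes")) {
    if (cfg[[i]] < 0) stop("'", i, "' must be >= 0")
  }
  invisible(cfg)
}

# flag <-> field vocabulary shared by parse_config and render_config
.config_flags <- c(
  "-c"    = "combined_mode",
  "-ns"   = "n_samples_per_ind",
  "-ad"   = "min_alt_depth",
  "-adss" = "min_alt_depth_single",
  "-vaf"  = "vaf_max",
  "-dp1"  = "depth_min",
  "-dp2"  = "depth_max",
  "-sr"   = "strand_ratio_max",
  "-pr"   = "pair_ratio_max",
  "-sp"   = "poisson_alpha",
  "-b"    = "binomial_alpha",
  "-nrl"  = "max_nearby_variants",
  "-hap"  = "max_haplotypes",
  "-cnv"  = "require_no_cnv",
  "-pir"  = "pir",
  "-vafq" = "vaf_recount_max",
  "-clip" = "clip_diff_max",
  "-mq"   = "mq_alpha",
  "-mm"   = "mismatch_alpha",
  "-pon"  = "pon_alpha"
)
.config_int_fields <- c("n_samples_per_ind", "min_alt_depth", "min_alt_depth_single",
                        "depth_min", "depth_max", "max_nearby_variants", "max_haplotypes")

#' Parse a filter parameter string
#'
#' Parses the compact flag/value vocabulary (see [filter_config()]) into a
#' \code{filter_config}. Omitted flags keep their defaults, so an empty string
#' returns the default configuration.
#'
#' @param arg_string a single string of flag/value pairs, e.g.
#'   \code{"-c BOTH -ns 4 -ad 2"}.
#' @return A \code{filter_config}.
#' @export
#' @examples
#' parse_config("-c SINGLE -adss 3 -vaf 0.5")
parse_config <- function(arg_string = "") {
  stopifnot(is.character(arg_string), length(arg_string) == 1)
  tok <- strsplit(trimws(arg_string), "[[:space:]]+")[[1]]
  tok <- tok[nzchar(tok)]
  if (length(tok) %% 2 != 0)
    stop("configuration error: flag without value in '", arg_string, "'")
  overrides <- list()
  for (i in if (length(tok)) seq(1, length(tok), by = 2) else integer(0)) {
    flag <- tok[i]; val <- tok[i + 1]
    if (!flag %in% names(.config_flags))
      stop("configuration error: unknown flag '", flag, "'")
    field <- .config_flags[[flag]]
    if (field == "combined_mode") {
      if (!val %in% c("SINGLE", "COMBINED", "BOTH"))
        stop("configuration error: -c must be SINGLE, COMBINED or BOTH")
      overrides$combined_mode <- val
    } else if (field == "require_no_cnv") {
      if (!val %in% c("NO", "IGNORE"))
        stop("configuration error: -cnv must be NO or IGNORE")
      overrides$require_no_cnv <- identical(val, "NO")
    } else if (field == "pir") {
      pair <- suppressWarnings(as.integer(strsplit(val, ",")[[1]]))
      if (length(pair) != 2 || anyNA(pair))
        stop("configuration error: -pir expects 'ref,alt' integers, got '", val, "'")
      overrides$pir_min_ref <- pair[1]
      overrides$pir_min_alt <- pair[2]
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop("configuration error: non-numeric value '", val, "' for flag ", flag)
      if (field %in% .config_int_fields) num <- as.integer(num)
      overrides[[field]] <- num
    }
  }
  do.call(filter_config, overrides)
}

#' Render a configuration back to its flag string
#'
#' Inverse of [parse_config()]: \code{parse_config(render_config(cfg))} equals
#' \code{cfg} for every valid configuration.
#'
#' @param cfg a \code{filter_config}.
#' @return A single string of flag/value pairs.
#' @export
render_config <- function(cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  parts <- character(0)
  for (flag in names(.config_flags)) {
    field <- .config_flags[[flag]]
    val <- switch(field,
      combined_mode  = cfg$combined_mode,
      require_no_cnv = if (cfg$require_no_cnv) "NO" else "IGNORE",
      pir            = paste0(cfg$pir_min_ref, ",", cfg$pir_min_alt),
      fmt(cfg[[field]]))
    parts <- c(parts, flag, val)
  }
  paste(parts, collapse = " ")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n  ", render_config(x), "\n", sep = "")
  invisible(x)
}
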