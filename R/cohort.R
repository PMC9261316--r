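#' Combined multi-sample decision over per-sample verdicts
#'
#' True somatic variants shared across tissues can fail individual filters in
#' individual samples by chance. The combined criterion requires, for EVERY
#' filter, that at least \code{n_required} of the individual's samples pass
#' it — allowing a different combination of passing samples at each filter.
#'
#' @param verdicts list of \code{filter_verdict} objects for one site, one
#'   per sample of the individual, all evaluated over the same filter set.
#' @param n_required samples required per filter.
#' @return Logical; TRUE when every filter reaches \code{n_required} passing
#'   samples. \code{n_required = 0} is vacuously TRUE; \code{n_required}
#'   above the sample count warns and returns FALSE.
#' @export
combined_decision <- function(verdicts, n_required) {
  if (n_required == 0) return(TRUE)
  if (n_required > length(verdicts)) {
    warning("n_required (", n_required, ") exceeds number of samples (", length(verdicts), ")")
    return(FALSE)
  }
  filters <- verdicts[[1]]$results$filter
  pass_mat <- vapply(verdicts, function(v) {
    v$results$pass[match(filters, v$results$filter)]
  }, logical(length(filters)))
  pass_mat <- matrix(pass_mat, nrow = length(filters))
  all(rowSums(pass_mat) >= n_required)
}

#' Resolve single/combined/both filtering modes for one site
#'
#' SINGLE passes when at least one sample passes every filter (verdicts
#' computed with the single-sample alt-depth threshold); COMBINED applies
#' [combined_decision()] (verdicts computed with the combined threshold);
#' BOTH is their disjunction.
#'
#' @param verdicts_single,verdicts_combined lists of per-sample
#'   \code{filter_verdict}s computed under the respective alt-depth
#'   thresholds.
#' @param cfg a \code{filter_config} (uses \code{combined_mode} and
#'   \code{n_samples_per_ind}).
#' @return An object of class \code{cohort_decision}: \code{mode_used},
#'   \code{single_pass_samples}, \code{combined_pass}, \code{final_pass}.
#' @export
resolve_mode <- function(verdicts_single, verdicts_combined, cfg) {
  single_samples <- names(verdicts_single)[vapply(verdicts_single, `[[`,
                                                  logical(1), "overall_pass")]
  if (is.null(single_samples))
    single_samples <- which(vapply(verdicts_single, `[[`, logical(1), "overall_pass"))
  single_pass <- length(single_samples) > 0
  combined_pass <- if (cfg$combined_mode %in% c("COMBINED", "BOTH")) {
    combined_decision(verdicts_combined, cfg$n_samples_per_ind)
  } else FALSE
  final <- switch(cfg$combined_mode,
                  SINGLE = single_pass,
                  COMBINED = combined_pass,
                  BOTH = single_pass || combined_pass)
  structure(list(mode_used = cfg$combined_mode,
                 single_pass_samples = single_samples,
                 single_pass = single_pass,
                 combined_pass = combined_pass,
                 final_pass = final), class = "cohort_decision")
}

#' Cross-individual recurrence filter (cohort panel)
#'
#' A variant supported by reads in other individuals of the cohort is
#' presumed germline or artifactual. Support for an individual means any of
#' its samples carries at least the configured number of alt reads.
#'
#' @param support_by_individual logical vector (or 0/1), one entry per OTHER
#'   individual: does that individual show alt support at this site?
#' @param max_recurrence maximum number of supporting other individuals
#'   tolerated (default 0).
#' @return list with \code{n_support} and \code{pass}.
#' @export
panel_recurrence <- function(support_by_individual, max_recurrence = 0L) {
  n <- sum(as.logical(support_by_individual))
  list(n_support = n, pass = n <= max_recurrence)
}

# Beta-binomial machinery ----------------------------------------------------

#' Fit a beta-binomial error model to panel counts
#'
#' Deterministic fitting chain: (1) method of moments on the pooled rate and
#' the variance of per-individual rates; (2) if the observed variance is at
#' or below binomial, fall back to a plain binomial with the pooled rate
#' (half-count pseudo-count keeps an all-zero panel away from a degenerate
#' zero rate); (3) if moments give non-positive shape parameters, maximum
#' likelihood via \code{optim}.
#'
#' @param k,n integer vectors of alt counts and depths per panel individual.
#' @return list with \code{method} ("betabinom" or "binomial") and either
#'   shapes \code{a}, \code{b} or rate \code{p}.
#' @export
fit_betabinomial <- function(k, n) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  if (length(k) < 2) stop("panel must have >= 2 individuals with depth > 0")
  p_hat <- sum(k) / sum(n)
  rates <- k / n
  s2 <- stats::var(rates)
  vb <- mean(p_hat * (1 - p_hat) / n)
  pooled <- list(method = "binomial", p = (sum(k) + 0.5) / (sum(n) + 1))
  if (!is.finite(s2) || s2 <= vb || p_hat == 0 || p_hat == 1) return(pooled)
  rho <- (s2 - vb) / (p_hat * (1 - p_hat) * mean((n - 1) / n))
  if (rho > 0 && rho < 1) {
    a <- p_hat * (1 - rho) / rho
    b <- (1 - p_hat) * (1 - rho) / rho
    if (a > 0 && b > 0) return(list(method = "betabinom", a = a, b = b))
  }
  # ML fallback on log-shape scale
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
  }
  fit <- stats::optim(c(0, log(max(1 / max(p_hat, 1e-6) - 1, 1e-6))), nll,
                      method = "Nelder-Mead")
  list(method = "betabinom", a = exp(fit$par[1]), b = exp(fit$par[2]))
}

#' Beta-binomial upper-tail probability
#'
#' P(X >= k) for X ~ BetaBinomial(n, a, b), by direct summation of the
#' probability mass.
#'
#' @param k threshold count.
#' @param n number of trials.
#' @param a,b shape parameters.
#' @return Tail probability.
#' @export
pbetabinom_upper <- function(k, n, a, b) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  x <- k:n
  sum(exp(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)))
}

#' Beta-binomial panel-of-normals test
#'
#' Fits a beta-binomial error model to the panel's per-individual allele
#' counts at the site and asks whether the observed sample's alt count
#' exceeds panel noise: p = P(X >= k_obs) under the fitted model, upper tail
#' only (panel support marks artifacts/germline; a true somatic shows excess
#' over near-zero panel noise). The filter requires SIGNIFICANCE.
#'
#' @param k_obs,n_obs observed alt count and informative depth.
#' @param panel a \code{panel_counts} object (vectors \code{k}, \code{n}).
#' @param alpha significance level.
#' @param empty_panel_policy what to do when the panel has no usable counts
#'   at the site: \code{"pass"} (default; annotated "no_pon") or
#'   \code{"fail"}.
#' @return list with \code{p_value}, \code{pass} and \code{note}.
#' @export
betabinomial_pon_test <- function(k_obs, n_obs, panel, alpha = 0.05,
                                  empty_panel_policy = c("pass", "fail")) {
  empty_panel_policy <- match.arg(empty_panel_policy)
  if (is.null(panel) || length(panel$k) < 2 || sum(panel$n > 0) < 2) {
    return(list(p_value = NA_real_, pass = empty_panel_policy == "pass", note = "no_pon"))
  }
  if (k_obs <= 0) return(list(p_value = 1, pass = FALSE, note = "no_alt_support"))
  fit <- fit_betabinomial(panel$k, panel$n)
  p <- if (fit$method == "binomial") {
    stats::pbinom(k_obs - 1, n_obs, fit$p, lower.tail = FALSE)
  } else {
    pbetabinom_upper(k_obs, n_obs, fit$a, fit$b)
  }
  list(p_value = p, pass = p < alpha, note = fit$method)
}
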