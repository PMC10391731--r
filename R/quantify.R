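#' Wilson score interval for a binomial proportion
#'
#' Computed via [stats::prop.test()] without continuity correction, whose
#' confidence interval is the Wilson score interval.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(estimate, lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf_level = 0.95) {
  if (n <= 0) return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  ci <- suppressWarnings(prop.test(x, n, conf.level = conf_level,
                                   correct = FALSE))$conf.int
  c(estimate = x / n, lower = ci[1L], upper = ci[2L])
}

#' Activation prevalence of the Braf-CA allele
#'
#' The fraction of Braf-CA molecules that are the activated (recombined)
#' form: activated families divided by total (native + activated) Braf-CA
#' families, computed on post-floor counts, with a Wilson 95% interval.
#'
#' @param counts An `allele_family_counts` object (after
#'   [apply_noise_floor()]); alternatively a named vector with elements
#'   `ca_native` and `ca_active`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `estimate`, `lower`, `upper`, `n` (denominator), and
#'   `reason` (`"ok"` or `"zero_denominator"`, in which case the estimate
#'   is `NA`).
#' @examples
#' activation_prevalence(c(ca_native = 30, ca_active = 10))$estimate
#' @export
activation_prevalence <- function(counts, conf_level = 0.95) {
  v <- counts_vector(counts)
  a <- v[["ca_active"]]; n <- v[["ca_native"]] + v[["ca_active"]]
  if (n <= 0)
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                n = 0L, reason = "zero_denominator"))
  w <- wilson_interval(a, n, conf_level)
  list(estimate = w[["estimate"]], lower = w[["lower"]], upper = w[["upper"]],
       n = as.integer(n), reason = "ok")
}

#' Mutant-cell fraction
#'
#' Estimates the fraction of cells carrying the activated allele by
#' referencing activated Braf-CA families to wildtype Braf families: under
#' the heterozygous model every cell contributes one wildtype template, so
#' families_active / families_wt estimates activated cells per cell. The
#' interval propagates the Wilson bounds of p = a/(a+w) through the
#' monotone map p/(1-p).
#'
#' @inheritParams activation_prevalence
#' @return A list: `estimate`, `lower`, `upper`, `n` (wildtype family
#'   count), `reason` (`"ok"` or `"zero_wildtype"`).
#' @examples
#' mutant_cell_fraction(c(wt = 10000, ca_native = 900, ca_active = 50))$estimate
#' @export
mutant_cell_fraction <- function(counts, conf_level = 0.95) {
  v <- counts_vector(counts)
  a <- v[["ca_active"]]; w <- v[["wt"]]
  if (w <= 0)
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                n = 0L, reason = "zero_wildtype"))
  wi <- wilson_interval(a, a + w, conf_level)
  odds <- function(p) ifelse(p >= 1, Inf, p / (1 - p))
  list(estimate = a / w, lower = odds(wi[["lower"]]),
       upper = odds(wi[["upper"]]), n = as.integer(w), reason = "ok")
}

counts_vector <- function(counts) {
  if (inherits(counts, "allele_family_counts")) return(counts$floored)
  if (is.numeric(counts)) {
    v <- c(wt = 0, ca_native = 0, ca_active = 0)
    v[names(counts)] <- counts
    return(v)
  }
  stop("counts must be allele_family_counts or a named numeric vector",
       call. = FALSE)
}

#' Welch two-group comparison of per-sample estimates
#'
#' Unpaired two-sample t test with unequal variances (Welch), as used for
#' comparing per-animal prevalence estimates between induced and
#' non-induced groups. Groups in which the values are constant (zero
#' variance) take a degenerate path reporting exact equality instead of a t
#' statistic.
#'
#' @param x,y Numeric vectors of per-sample estimates (each length >= 2).
#' @return A list: `difference` (mean(x) - mean(y)), `t`, `df`, `p_value`,
#'   `method` (`"welch"` or `"degenerate"`), and for the degenerate path
#'   `identical` (`TRUE` when all values in both groups are equal).
#' @examples
#' compare_groups(c(1, 2, 3), c(11, 12, 13))
#' @export
compare_groups <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    return(list(difference = mean(x) - mean(y), t = NA_real_, df = NA_real_,
                p_value = NA_real_, method = "degenerate",
                identical = length(unique(c(x, y))) == 1L))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(difference = mean(x) - mean(y), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, method = "welch")
}

#' Build the per-sample quantification report row
#'
#' @param counts An `allele_family_counts` object with the floor applied.
#' @param read_counts Optional named vector of per-allele *read* counts
#'   (pre-deduplication), reported alongside for comparison.
#' @param conf_level Confidence level for intervals.
#' @return A one-row data.frame (class `quant_report`) with raw and floored
#'   family counts, activation prevalence and mutant-cell fraction with
#'   Wilson 95% bounds, reason codes, and the read-based prevalence.
#' @export
quant_report <- function(counts, read_counts = NULL, conf_level = 0.95) {
  stopifnot(inherits(counts, "allele_family_counts"))
  prev <- activation_prevalence(counts, conf_level)
  mcf <- mutant_cell_fraction(counts, conf_level)
  raw_prev <- if (sum(counts$raw[c("ca_native", "ca_active")]) > 0)
    counts$raw[["ca_active"]] / sum(counts$raw[c("ca_native", "ca_active")])
  else NA_real_
  reads_prev <- if (!is.null(read_counts) &&
                    sum(read_counts[c("ca_native", "ca_active")]) > 0)
    unname(read_counts[["ca_active"]] /
           sum(read_counts[c("ca_native", "ca_active")]))
  else NA_real_
  out <- data.frame(
    sample_id = counts$sample_id,
    families_wt = counts$raw[["wt"]],
    families_native = counts$raw[["ca_native"]],
    families_active = counts$raw[["ca_active"]],
    families_wt_floored = counts$floored[["wt"]],
    families_native_floored = counts$floored[["ca_native"]],
    families_active_floored = counts$floored[["ca_active"]],
    suppressed_active = counts$suppressed[["ca_active"]],
    prevalence = prev$estimate, prevalence_lo = prev$lower,
    prevalence_hi = prev$upper, prevalence_reason = prev$reason,
    prevalence_raw = raw_prev, prevalence_reads = reads_prev,
    mutant_cell_fraction = mcf$estimate, mcf_lo = mcf$lower,
    mcf_hi = mcf$upper, mcf_reason = mcf$reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("quant_report", class(out))
  out
}
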