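#' False-negative rate from ancestral-heterozygote recall
#'
#' Every high-quality heterozygous locus of the ancestor should reappear in
#' each clonally produced offspring; loci not recovered bound the pipeline's
#' false-negative rate from above (true loss of heterozygosity inflates the
#' estimate). The ancestor het set must be built with the same thresholds
#' as candidate calling: depth inside `[min_depth, max_depth]` and at least
#' `min_reads` reads per allele. Per-offspring miss fractions are averaged
#' and a t-interval (n - 1 df) across offspring gives the CI.
#'
#' @param ancestor_hets Tibble `chrom, pos` of ancestral het loci.
#' @param offspring_calls Site-call tibble restricted to offspring samples.
#' @param min_depth,max_depth Callable band for a recovered het.
#' @param min_reads Minimum reads per allele for a recovered het.
#' @param conf Confidence level.
#' @return One-row tibble of class `fn_estimate`: `method, rate, ci_low,
#'   ci_high, n_trials, n_missed`; attribute `per_sample` holds
#'   per-offspring miss fractions.
#' @export
het_recall_fn <- function(ancestor_hets, offspring_calls,
                          min_depth = 9, max_depth = 75, min_reads = 3,
                          conf = 0.95) {
  offspring <- unique(offspring_calls$sample)
  if (length(offspring) == 0) abort("no offspring samples")
  n_het <- nrow(ancestor_hets)
  if (n_het == 0) abort("empty ancestor het set")

  per <- purrr::map_dfr(offspring, function(sm) {
    rec <- offspring_calls %>%
      filter(.data$sample == sm, .data$gt == "het",
             .data$dp >= min_depth, .data$dp <= max_depth,
             .data$ad_ref >= min_reads, .data$ad_alt >= min_reads) %>%
      semi_join(ancestor_hets, by = c("chrom", "pos"))
    tibble(sample = sm, n_assayed = n_het,
           n_missed = n_het - nrow(distinct(rec, .data$chrom, .data$pos)))
  }) %>%
    mutate(miss_frac = .data$n_missed / .data$n_assayed)

  m <- mean(per$miss_frac)
  n_off <- nrow(per)
  se <- if (n_off > 1) sd(per$miss_frac) / sqrt(n_off) else 0
  tq <- if (n_off > 1) qt(1 - (1 - conf) / 2, n_off - 1) else 0
  out <- tibble(method = "het_recall", rate = m,
                ci_low = max(0, m - tq * se),
                ci_high = min(1, m + tq * se),
                n_trials = n_het * n_off,
                n_missed = sum(per$n_missed))
  attr(out, "per_sample") <- per
  class(out) <- c("fn_estimate", class(out))
  out
}

#' False-negative rate from spike-in recall
#'
#' Compares a spike-in truth set with the candidates the pipeline
#' recovered: FN = missed / spiked, with exact Poisson (Garwood) bounds on
#' the missed count scaled by the number of trials. Printed counts can be
#' supplied directly via `n_missed` / `n_trials` instead of tables.
#'
#' @param truth A `sim_truth` (or tibble `sample, chrom, pos`) of spiked
#'   variants.
#' @param recovered Candidate tibble with `sample, chrom, pos`.
#' @param n_missed,n_trials Direct counts, as an alternative to tables.
#' @param alpha Two-sided error rate.
#' @return One-row tibble of class `fn_estimate`.
#' @export
#' @examples
#' spikein_fn(n_missed = 55, n_trials = 1000)  # 5.5% (4.1-7.2%)
spikein_fn <- function(truth = NULL, recovered = NULL,
                       n_missed = NULL, n_trials = NULL, alpha = 0.05) {
  if (is.null(n_missed) || is.null(n_trials)) {
    if (is.null(truth)) abort("supply `truth` or direct counts")
    spiked <- if (inherits(truth, "sim_truth")) truth$spiked else truth
    if (nrow(spiked) == 0) abort("empty spike-in truth")
    n_trials <- nrow(spiked)
    if (is.null(recovered) || nrow(recovered) == 0) {
      n_missed <- n_trials
    } else {
      hit <- paste(spiked$sample, spiked$chrom, spiked$pos) %in%
        paste(recovered$sample, recovered$chrom, recovered$pos)
      n_missed <- sum(!hit)
    }
  }
  ci <- poisson_ci(n_missed, alpha)
  out <- tibble(method = "spike_in", rate = n_missed / n_trials,
                ci_low = ci$lower / n_trials,
                ci_high = ci$upper / n_trials,
                n_trials = as.integer(n_trials),
                n_missed = as.integer(n_missed))
  class(out) <- c("fn_estimate", class(out))
  out
}

#' @export
print.fn_estimate <- function(x, ...) {
  cat(sprintf("False-negative rate (%s): %s\n", x$method, format_fn(x)))
  invisible(as_tibble(x))
}

#' Format a false-negative estimate as "mean% (95% CI low-high%)"
#'
#' @param x An `fn_estimate`.
#' @return A character scalar.
#' @export
format_fn <- function(x) {
  sprintf("%.1f%% (95%% CI %.1f-%.1f%%)",
          100 * x$rate, 100 * x$ci_low, 100 * x$ci_high)
}

#' Adjust treatment rates for a known false-negative rate
#'
#' Divides rates (mean and interval) by `1 - fn`, inflating them to account
#' for mutations the pipeline misses. The output is flagged `adjusted`.
#'
#' @param rates A `treatment_rates` tibble.
#' @param fn An `fn_estimate` or a numeric FN fraction in \[0, 1).
#' @return The rates tibble with adjusted values and `adjusted = TRUE`.
#' @export
fn_correct_rate <- function(rates, fn) {
  f <- if (inherits(fn, "fn_estimate") || is.data.frame(fn)) fn$rate[1] else fn
  if (f < 0 || f >= 1) abort("fn rate must lie in [0, 1)")
  out <- rates %>%
    mutate(mean_rate = .data$mean_rate / (1 - f),
           ci_low = .data$ci_low / (1 - f),
           ci_high = .data$ci_high / (1 - f),
           adjusted = TRUE)
  attr(out, "fn_rate") <- f
  out
}
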