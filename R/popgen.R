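#' Construct a genotype matrix
#'
#' Light container for a samples-by-sites allele-dosage matrix with
#' positions, optional population labels, a callable length for per-site
#' scaling, and ploidy (1 for haplotypes, 2 for unphased diploids; dosage
#' is the alternate-allele count, `0..ploidy`, `NA` for missing).
#'
#' @param dosage Numeric matrix, samples x sites.
#' @param positions 1-based site positions (strictly increasing).
#' @param pop Optional population label per sample.
#' @param callable_length Sites assayed (denominator for per-site
#'   diversity); defaults to `ncol(dosage)`.
#' @param ploidy 1 or 2.
#' @return A list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, positions = seq_len(ncol(dosage)),
                            pop = NULL, callable_length = ncol(dosage),
                            ploidy = 2) {
  dosage <- as.matrix(dosage)
  if (length(positions) != ncol(dosage)) {
    abort("`positions` must match the number of sites")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("`positions` must be strictly increasing")
  }
  if (any(dosage < 0 | dosage > ploidy, na.rm = TRUE)) {
    abort("dosages must lie in [0, ploidy]")
  }
  if (callable_length <= 0) abort("`callable_length` must be > 0")
  structure(list(dosage = dosage, positions = positions, pop = pop,
                 callable_length = callable_length, ploidy = ploidy),
            class = "genotype_matrix")
}

#' Convert a coalescent sample to a genotype matrix
#'
#' Haplotypes map directly (`ploidy = 1`); with `ploidy = 2` consecutive
#' haplotype pairs are combined into unphased diploids. Relative
#' coordinates in \[0,1) are kept, scaled to integer positions over
#' `locus_length` bp. The default `callable_length = 1` makes
#' [nucleotide_diversity()] return per-locus diversity, whose neutral
#' expectation is theta.
#'
#' @param cs A `coalescent_sample`.
#' @param ploidy 1 or 2 (requires an even haplotype count).
#' @param callable_length Denominator for per-site scaling.
#' @param locus_length Length in bp used to place sites on an integer grid.
#' @return A `genotype_matrix`.
#' @export
as_genotype_matrix <- function(cs, ploidy = 1, callable_length = 1,
                               locus_length = 1e6) {
  stopifnot(inherits(cs, "coalescent_sample"))
  hap <- cs$haplotypes
  pos <- as.integer(floor(cs$positions * locus_length)) + 1L
  # infinite-sites positions can collide after discretisation; nudge apart
  while (anyDuplicated(pos)) pos[duplicated(pos)] <- pos[duplicated(pos)] + 1L
  ord <- order(pos)
  hap <- hap[, ord, drop = FALSE]
  pos <- pos[ord]
  if (ploidy == 2) {
    if (nrow(hap) %% 2 != 0) abort("diploid pairing needs an even haplotype count")
    odd <- seq(1, nrow(hap), by = 2)
    hap <- hap[odd, , drop = FALSE] + hap[odd + 1, , drop = FALSE]
  }
  genotype_matrix(hap, positions = pos, callable_length = callable_length,
                  ploidy = ploidy)
}

# per-site unbiased heterozygosity 2p(1-p) * n/(n-1) from a dosage matrix
site_heterozygosity <- function(dosage, ploidy) {
  n_called <- colSums(!is.na(dosage)) * ploidy
  ac <- colSums(dosage, na.rm = TRUE)
  p <- ifelse(n_called > 0, ac / n_called, NA_real_)
  h <- 2 * p * (1 - p) * n_called / (n_called - 1)
  h[n_called < 2] <- NA_real_
  h
}

#' Per-site nucleotide diversity (pi)
#'
#' Average pairwise difference per site: the per-site unbiased
#' heterozygosity `2p(1-p) n/(n-1)` (n = number of called alleles; missing
#' genotypes reduce n at that site) summed over segregating sites and
#' divided by `callable_length`.
#'
#' @param g A `genotype_matrix` with at least 2 samples.
#' @return Numeric pi.
#' @export
nucleotide_diversity <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosage) < 2) abort("need >= 2 samples")
  h <- site_heterozygosity(g$dosage, g$ploidy)
  sum(h, na.rm = TRUE) / g$callable_length
}

#' Cohort-level depth filter
#'
#' Keeps sites whose cohort depth `DP` lies strictly between `min_dp` and
#' `max_dp`; an optional interval mask (e.g. organelle regions) removes
#' sites it covers.
#'
#' @param calls Site-call tibble with a `dp_site` column.
#' @param min_dp,max_dp Exclusive cohort-depth bounds.
#' @param exclude_mask Optional tibble `chrom, start, end` (0-based
#'   half-open) of regions to drop.
#' @return Filtered tibble.
#' @export
cohort_depth_filter <- function(calls, min_dp = 510, max_dp = 10200,
                                exclude_mask = NULL) {
  out <- calls %>% filter(.data$dp_site > min_dp, .data$dp_site < max_dp)
  if (!is.null(exclude_mask) && nrow(exclude_mask) > 0 && nrow(out) > 0) {
    excl <- vapply(seq_len(nrow(out)), function(i) {
      any(exclude_mask$chrom == out$chrom[i] &
            exclude_mask$start < out$pos[i] & out$pos[i] <= exclude_mask$end)
    }, logical(1))
    out <- out[!excl, , drop = FALSE]
  }
  out
}

#' Tajima's D from summary quantities
#'
#' Standardized difference between the pairwise estimator of theta
#' (`pi_total`, the mean number of pairwise differences per locus) and
#' Watterson's `S/a1`, using the standard constants a1, a2, b1, b2, c1,
#' c2, e1, e2 derived from the number of sequences. Near 0 under neutral
#' equilibrium. Undefined at S = 0 (returns `NA` with a warning).
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences (>= 4).
#' @param pi_total Mean pairwise differences per locus (not per site).
#' @return Numeric D (or `NA` when S = 0).
#' @export
tajimas_d <- function(S, n, pi_total) {
  if (n < 4) abort("Tajima's D needs n >= 4 sequences")
  if (S == 0) {
    warn("Tajima's D undefined when S = 0")
    return(NA_real_)
  }
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Diversity summary for a genotype matrix
#'
#' @param g A `genotype_matrix`.
#' @return One-row tibble: `pi` (per site), `pi_total` (per locus), `S`,
#'   `theta_w` (Watterson, per site), `tajimas_d`, `n_sequences`,
#'   `callable_length`.
#' @export
diversity_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  h <- site_heterozygosity(g$dosage, g$ploidy)
  seg <- which(!is.na(h) & h > 0)
  S <- length(seg)
  pi_total <- sum(h, na.rm = TRUE)
  n_seq <- nrow(g$dosage) * g$ploidy
  a1 <- sum(1 / seq_len(n_seq - 1))
  D <- if (S > 0 && n_seq >= 4) tajimas_d(S, n_seq, pi_total) else NA_real_
  tibble(pi = pi_total / g$callable_length, pi_total = pi_total, S = S,
         theta_w = S / a1 / g$callable_length, tajimas_d = D,
         n_sequences = n_seq, callable_length = g$callable_length)
}

#' Hudson's Fst between two populations
#'
#' Ratio-of-averages estimator: `Fst = 1 - mean(pi_within) /
#' mean(pi_between)` across sites, where within-population diversity is the
#' average of the two populations' unbiased per-site heterozygosities and
#' between-population diversity is `p1(1-p2) + p2(1-p1)`. Undefined when
#' mean between-population diversity is zero.
#'
#' @param a,b `genotype_matrix` objects over the same sites (>= 2 samples
#'   each).
#' @return Numeric Fst in (-Inf, 1].
#' @export
pairwise_fst <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  if (nrow(a$dosage) < 2 || nrow(b$dosage) < 2) abort("need >= 2 samples per population")
  if (ncol(a$dosage) != ncol(b$dosage)) abort("populations must share the site set")
  freq <- function(g) {
    n <- colSums(!is.na(g$dosage)) * g$ploidy
    list(p = colSums(g$dosage, na.rm = TRUE) / n, n = n)
  }
  fa <- freq(a); fb <- freq(b)
  hw <- (site_heterozygosity(a$dosage, a$ploidy) +
           site_heterozygosity(b$dosage, b$ploidy)) / 2
  hb <- fa$p * (1 - fb$p) + fb$p * (1 - fa$p)
  ok <- !is.na(hw) & !is.na(hb)
  if (!any(ok) || mean(hb[ok]) == 0) {
    abort("between-population diversity is zero; Fst undefined")
  }
  1 - mean(hw[ok]) / mean(hb[ok])
}

#' Pairwise LD (r-squared) against physical distance
#'
#' Unphased genotype-dosage correlation (Rogers-Huff): for every pair of
#' sites within `max_distance`, r is the Pearson correlation of the two
#' dosage vectors over samples called at both sites. Sites with minor
#' allele frequency below `maf_min` or with zero dosage variance are
#' dropped first.
#'
#' @param g A single-chromosome `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (exclusive: MAF must
#'   exceed this).
#' @param max_distance Maximum inter-site distance in bp (default 100 kb).
#' @return Tibble `pos1, pos2, distance, r2`.
#' @export
ld_r2 <- function(g, maf_min = 0.05, max_distance = 1e5) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_al <- colSums(!is.na(g$dosage)) * g$ploidy
  p <- colSums(g$dosage, na.rm = TRUE) / n_al
  maf <- pmin(p, 1 - p)
  v <- apply(g$dosage, 2, var, na.rm = TRUE)
  keep <- which(maf > maf_min & !is.na(v) & v > 0)
  if (length(keep) < 2) {
    return(tibble(pos1 = integer(), pos2 = integer(),
                  distance = integer(), r2 = numeric()))
  }
  d <- g$dosage[, keep, drop = FALSE]
  pos <- g$positions[keep]
  cc <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  out <- tibble(pos1 = pos[idx[, 1]], pos2 = pos[idx[, 2]],
                distance = abs(pos[idx[, 2]] - pos[idx[, 1]]),
                r2 = cc[idx]^2)
  out %>% filter(.data$distance <= max_distance, !is.na(.data$r2))
}

#' Bin LD pairs into non-overlapping distance windows
#'
#' @param pairs Tibble from [ld_r2()].
#' @param bin_width Bin width in bp (default 100).
#' @param max_distance Optional truncation.
#' @return Tibble `midpoint, mean_r2, n_pairs`; empty bins are omitted.
#' @export
bin_ld <- function(pairs, bin_width = 100, max_distance = NULL) {
  if (nrow(pairs) == 0) abort("no LD pairs to bin")
  if (!is.null(max_distance)) {
    pairs <- pairs %>% filter(.data$distance <= max_distance)
  }
  pairs %>%
    mutate(bin = floor(.data$distance / bin_width)) %>%
    group_by(.data$bin) %>%
    summarise(midpoint = .data$bin[1] * bin_width + bin_width / 2,
              mean_r2 = mean(.data$r2), n_pairs = n(), .groups = "drop") %>%
    select("midpoint", "mean_r2", "n_pairs") %>%
    arrange(.data$midpoint)
}

#' Fit Sved's LD-decay equation to binned r-squared
#'
#' Weighted least squares of `E(r2) = 1/(1 + 4 beta d) + 1/n` over bin
#' means (d = bin midpoint, weights = pair counts), with the decay
#' parameter constrained to `beta >= 0` and `1/n` the small-sample
#' correction for `n` sampled individuals. A flat series at `1/n` returns
#' the boundary `beta = 0`.
#'
#' @param bins Tibble from [bin_ld()] (>= 3 bins).
#' @param n Sample size used in the 1/n correction; `n = Inf` drops the
#'   correction.
#' @return A list of class `sved_fit`: `beta`, `n`, `rss`, `bins` (with
#'   fitted values).
#' @export
fit_sved <- function(bins, n) {
  if (nrow(bins) < 3) abort("need >= 3 bins to fit")
  corr <- if (is.finite(n)) 1 / n else 0
  y <- bins$mean_r2 - corr
  w <- bins$n_pairs
  d <- bins$midpoint
  if (all(abs(y - y[1]) < 1e-12)) {
    beta <- 0
  } else {
    # half-decay heuristic start: d where the excess falls to half its max
    y0 <- max(y)
    half <- d[which.min(abs(y - y0 / 2))]
    b0 <- if (half > 0) 1 / (4 * half) else 1e-4
    fit <- try(minpack.lm::nlsLM(
      mean_r2 ~ 1 / (1 + 4 * beta * midpoint) + corr,
      data = cbind(bins, corr = corr),
      start = list(beta = b0), lower = 0, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    beta <- if (inherits(fit, "try-error")) {
      # fall back to a bounded 1-D search
      obj <- function(b) sum(w * (1 / (1 + 4 * b * d) + corr - bins$mean_r2)^2)
      optimize(obj, c(0, max(1, 10 / max(d))), tol = 1e-14)$minimum
    } else {
      stats::coef(fit)[["beta"]]
    }
  }
  fitted <- 1 / (1 + 4 * beta * d) + corr
  rss <- sum(w * (bins$mean_r2 - fitted)^2)
  structure(list(beta = beta, n = n, rss = rss,
                 bins = bins %>% mutate(fitted = fitted)),
            class = "sved_fit")
}

#' @export
print.sved_fit <- function(x, ...) {
  cat(sprintf("Sved LD-decay fit: beta = %.4g per bp, n = %s, rss = %.4g\n",
              x$beta, format(x$n), x$rss))
  invisible(x)
}

#' @rdname fit_sved
#' @param x A `sved_fit`.
#' @param ... Unused.
#' @method tidy sved_fit
#' @export
tidy.sved_fit <- function(x, ...) {
  tibble(term = "beta", estimate = x$beta)
}

#' @rdname fit_sved
#' @method glance sved_fit
#' @export
glance.sved_fit <- function(x, ...) {
  tibble(beta = x$beta, n = x$n, rss = x$rss, n_bins = nrow(x$bins))
}

#' @rdname fit_sved
#' @param object A `sved_fit`.
#' @method autoplot sved_fit
#' @export
autoplot.sved_fit <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$midpoint)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_r2,
                                     size = .data$n_pairs), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "distance (bp)", y = expression(mean ~ r^2),
                  size = "pairs",
                  title = sprintf("LD decay (beta = %.3g /bp)", object$beta)) +
    ggplot2::theme_minimal()
}

#' Distance at which fitted LD decays to a target r-squared
#'
#' Analytic inversion of the fitted model:
#' `d = (1/(r2_target - 1/n) - 1) / (4 beta)`. The conventional
#' "useful LD for mapping" target is r2 = 0.33.
#'
#' @param fit A `sved_fit`.
#' @param r2_target Target r-squared (must exceed `1/n`).
#' @return Distance in bp (`Inf` with a warning when `beta = 0`).
#' @export
ld_distance_at <- function(fit, r2_target = 0.33) {
  stopifnot(inherits(fit, "sved_fit"))
  corr <- if (is.finite(fit$n)) 1 / fit$n else 0
  if (r2_target <= corr) {
    abort("`r2_target` must exceed the 1/n correction; unreachable under the model")
  }
  if (fit$beta == 0) {
    warn("beta = 0: LD never decays to the target")
    return(Inf)
  }
  (1 / (r2_target - corr) - 1) / (4 * fit$beta)
}
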