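# hand-built site-call rows for filter tests
make_site <- function(pos, samples_gt, ref = "A", alt = "T",
                      qual = 500, qd = 25, mq0 = 0L, dp = 28L,
                      ad = NULL, insert = 350L, proper = 1.0) {
  purrr::imap_dfr(samples_gt, function(gt, sm) {
    adr <- if (!is.null(ad) && sm %in% names(ad)) ad[[sm]][1] else {
      switch(gt, het = dp %/% 2L, hom_ref = dp, hom_alt = 0L, missing = 0L)
    }
    ada <- if (!is.null(ad) && sm %in% names(ad)) ad[[sm]][2] else {
      switch(gt, het = dp - dp %/% 2L, hom_ref = 0L, hom_alt = dp,
             missing = 0L)
    }
    tibble::tibble(chrom = "chr1", pos = as.integer(pos), ref = ref,
                   alt = alt, qual = qual, qd = qd, mq0 = as.integer(mq0),
                   dp_site = dp * length(samples_gt), sample = sm, gt = gt,
                   ad_ref = as.integer(adr), ad_alt = as.integer(ada),
                   dp = as.integer(adr + ada),
                   proper_pair_fraction = proper,
                   median_insert = as.integer(insert))
  })
}

# brute-force oracles, deliberately naive
oracle_callable <- function(depth, lo = 9, hi = 75) {
  sum(vapply(depth, function(d) d >= lo && d <= hi, logical(1)))
}

oracle_cluster_flags <- function(pos, window = 50, min_count = 3) {
  pos <- sort(pos)
  flag <- logical(length(pos))
  for (i in seq_along(pos)) {
    for (j in seq_along(pos)) {
      if (j >= i && pos[j] - pos[i] <= window && (j - i + 1) >= min_count) {
        flag[i:j] <- TRUE
      }
    }
  }
  flag
}

# exact Poisson bounds by direct inversion of the Poisson CDF (independent
# of the chi-square identity used in the implementation)
oracle_poisson_ci <- function(k, alpha = 0.05) {
  tol <- .Machine$double.eps^0.75
  upper <- stats::uniroot(function(l) ppois(k, l) - alpha / 2,
                          c(1e-9, 10 * k + 50), tol = tol)$root
  lower <- if (k == 0) 0 else {
    stats::uniroot(function(l) 1 - ppois(k - 1, l) - alpha / 2,
                   c(1e-12, 10 * k + 50), tol = tol)$root
  }
  c(lower = lower, upper = upper)
}

# per-codon synonymous-site count by enumerating all 9 single-base changes
oracle_codon_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] == code[[codon]]) syn <- syn + 1 / 3
    }
  }
  syn
}
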