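#' Hard site filters for a multi-sample call table
#'
#' Removes a site when (`MQ0 >= mq0_count` AND `MQ0/DP > mq0_frac`) OR
#' `QUAL < min_qual` OR `QD < min_qd` — the standard GATK-style hard filter
#' for mapping-quality-zero pile-ups, low variant confidence, and low
#' quality-by-depth. Only biallelic sites are retained. Sites with missing
#' annotations are not silently kept: they are dropped from the output and
#' returned in the `unevaluable` attribute.
#'
#' Any clause can be disabled by passing `NULL` for its threshold.
#'
#' @param calls Site-call tibble (columns `chrom, pos, ref, alt, qual, qd,
#'   mq0, dp_site`, plus per-sample columns).
#' @param min_qual,min_qd,mq0_count,mq0_frac Filter thresholds.
#' @return Filtered tibble; attribute `unevaluable` holds sites whose
#'   annotations could not be evaluated.
#' @export
hard_filter_sites <- function(calls, min_qual = 30, min_qd = 5,
                              mq0_count = 4, mq0_frac = 0.1) {
  if (nrow(calls) == 0) return(calls)
  sites <- calls %>%
    distinct(.data$chrom, .data$pos, .data$alt, .keep_all = TRUE) %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(n_alt = n_distinct(.data$alt),
              qual = .data$qual[1], qd = .data$qd[1], mq0 = .data$mq0[1],
              dp_site = .data$dp_site[1], .groups = "drop")
  unev <- sites %>%
    filter(is.na(.data$qual) | is.na(.data$qd) | is.na(.data$mq0) |
             is.na(.data$dp_site))
  if (nrow(unev) > 0) {
    inform(sprintf("%d site(s) with missing annotations set aside.",
                   nrow(unev)))
  }
  ev <- sites %>% anti_join(unev, by = c("chrom", "pos"))
  fail_mq0 <- if (is.null(mq0_count) || is.null(mq0_frac)) {
    rep(FALSE, nrow(ev))
  } else {
    ev$mq0 >= mq0_count & ev$mq0 / ev$dp_site > mq0_frac
  }
  fail_qual <- if (is.null(min_qual)) rep(FALSE, nrow(ev)) else ev$qual < min_qual
  fail_qd <- if (is.null(min_qd)) rep(FALSE, nrow(ev)) else ev$qd < min_qd
  keep <- ev %>% filter(!fail_mq0 & !fail_qual & !fail_qd,
                        .data$n_alt == 1L)
  out <- calls %>% semi_join(keep, by = c("chrom", "pos"))
  attr(out, "unevaluable") <- calls %>%
    semi_join(unev, by = c("chrom", "pos"))
  out
}

#' Read-support (proper-pair / insert-size) filter
#'
#' Per-sample records whose supporting reads do not look like properly
#' paired fragments with insert size strictly between `min_insert` and
#' `max_insert` bp have their depths zeroed (genotype set to missing), so
#' they contribute neither to candidacy nor to callable-site computation.
#' Records with absent summaries are treated as passing and counted in a
#' message.
#'
#' @param calls Site-call tibble.
#' @param min_insert,max_insert Exclusive insert-size bounds in bp.
#' @param require_proper Require a high properly-paired fraction.
#' @param min_proper_frac Minimum proper-pair fraction when
#'   `require_proper` is `TRUE`.
#' @return Tibble with failing records zeroed.
#' @export
filter_read_support <- function(calls, min_insert = 100, max_insert = 600,
                                require_proper = TRUE,
                                min_proper_frac = 0.9) {
  if (nrow(calls) == 0) return(calls)
  absent <- is.na(calls$median_insert) & is.na(calls$proper_pair_fraction)
  if (any(absent)) {
    inform(sprintf("%d record(s) without read-support summaries pass through.",
                   sum(absent)))
  }
  fail <- (!is.na(calls$median_insert) &
             (calls$median_insert <= min_insert |
                calls$median_insert >= max_insert)) |
    (require_proper & !is.na(calls$proper_pair_fraction) &
       calls$proper_pair_fraction < min_proper_frac)
  calls %>% mutate(
    ad_ref = if_else(fail, 0L, .data$ad_ref),
    ad_alt = if_else(fail, 0L, .data$ad_alt),
    dp = if_else(fail, 0L, .data$dp),
    gt = if_else(fail, "missing", .data$gt)
  )
}

#' Callable-site masks from depth profiles
#'
#' A position is callable when its per-sample depth lies inside
#' `[min_depth, max_depth]` (defaults 9 and 75 reads, inclusive: positions
#' with fewer than nine or more than 75 reads are excluded). Contiguous
#' callable runs are merged into 0-based half-open intervals.
#'
#' @param depth A numeric depth vector (positions 1..L of one sample on one
#'   chromosome), or a named list of such vectors (one per sample).
#' @param min_depth,max_depth Inclusive callable band.
#' @param chrom Chromosome label for the emitted intervals.
#' @return Tibble of class `callable_mask` with columns
#'   `sample, chrom, start, end` (0-based half-open); use
#'   [total_callable()] for per-sample site counts.
#' @export
#' @examples
#' compute_callable(c(5, 9, 75, 76))  # middle two positions callable
compute_callable <- function(depth, min_depth = 9, max_depth = 75,
                             chrom = "chr1") {
  if (is.list(depth)) {
    if (is.null(names(depth))) abort("depth list must be named by sample")
    out <- purrr::imap_dfr(depth, function(d, nm) {
      compute_callable(d, min_depth, max_depth, chrom) %>%
        mutate(sample = nm)
    })
    return(structure(out %>% select("sample", "chrom", "start", "end"),
                     class = c("callable_mask", class(tibble()))))
  }
  if (any(depth < 0)) abort("negative depth")
  ok <- depth >= min_depth & depth <= max_depth
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  out <- tibble(sample = NA_character_, chrom = chrom,
                start = starts[keep], end = ends[keep])
  structure(out, class = c("callable_mask", class(tibble())))
}

#' Per-sample callable-site totals
#'
#' @param mask A callable-mask tibble from [compute_callable()].
#' @return Tibble with `sample` and `total` (summed interval lengths,
#'   the rate denominator L).
#' @export
total_callable <- function(mask) {
  mask %>%
    group_by(.data$sample) %>%
    summarise(total = sum(.data$end - .data$start), .groups = "drop")
}

# is 1-based position pos inside a sample's mask?
in_mask <- function(mask, sample, chrom, pos) {
  m <- mask[mask$sample == sample & mask$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(m$start < p & p <= m$end), logical(1))
}

#' Flag variant clusters
#'
#' Flags every variant that belongs to any window of `window` bp containing
#' at least `min_count` distinct variant sites (positions p_i..p_j with
#' p_j - p_i <= window). Clustered variants are overwhelmingly alignment
#' artifacts in MA data and are removed from candidacy. Set
#' `min_count = 4` for a literal "more than three variants" reading.
#'
#' @param calls Site-call tibble (sorted internally if needed).
#' @param window Window size in bp.
#' @param min_count Minimum variants in a window for flagging.
#' @return Input tibble with a logical `cluster_flag` column.
#' @export
annotate_clusters <- function(calls, window = 50, min_count = 3) {
  if (nrow(calls) == 0) {
    return(calls %>% mutate(cluster_flag = logical(0)))
  }
  if (is.unsorted(order(calls$chrom, calls$pos))) {
    inform("calls not sorted by (chrom, pos); sorting internally.")
  }
  sites <- calls %>% distinct(.data$chrom, .data$pos) %>%
    arrange(.data$chrom, .data$pos)
  flagged <- sites %>%
    group_by(.data$chrom) %>%
    mutate(flag = cluster_flags(.data$pos, window, min_count)) %>%
    ungroup()
  calls %>%
    left_join(flagged, by = c("chrom", "pos")) %>%
    rename(cluster_flag = "flag")
}

# windowed two-pointer scan over sorted positions
cluster_flags <- function(pos, window, min_count) {
  n <- length(pos)
  flag <- logical(n)
  j <- 1L
  for (i in seq_len(n)) {
    while (j <= n && pos[j] - pos[i] <= window) j <- j + 1L
    if (j - i >= min_count) flag[i:(j - 1L)] <- TRUE
  }
  flag
}

#' Cross-sample sharing filter
#'
#' A true de novo mutation arises in one line; the chance of the same
#' position mutating independently in several lines is negligible, so any
#' variant carried (non-hom-ref genotype) by more than `max_samples`
#' individuals is removed as an artifact. The ancestor counts as a carrier
#' by default.
#'
#' @param calls Site-call tibble.
#' @param max_samples Maximum number of carrier samples.
#' @param include_ancestor Count the ancestor among carriers.
#' @param ancestor Ancestor sample id (needed when
#'   `include_ancestor = FALSE`).
#' @return Filtered tibble.
#' @export
cross_sample_filter <- function(calls, max_samples = 2,
                                include_ancestor = TRUE, ancestor = NULL) {
  if (nrow(calls) == 0) return(calls)
  counted <- calls
  if (!include_ancestor) {
    if (is.null(ancestor)) abort("`ancestor` required when excluded from counting")
    counted <- counted %>% filter(.data$sample != ancestor)
  }
  carriers <- counted %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(n_carrier = sum(.data$gt %in% c("het", "hom_alt")),
              .groups = "drop")
  keep <- carriers %>% filter(.data$n_carrier <= max_samples)
  calls %>% semi_join(keep, by = c("chrom", "pos"))
}

#' Heterozygote allele-support filter
#'
#' Heterozygous per-sample records must be supported by at least
#' `min_reads` reads for *both* alleles; failing het records are set to
#' missing, and sites left without any variant carrier are dropped.
#' Homozygous records are not subject to this filter.
#'
#' @param calls Site-call tibble.
#' @param min_reads Minimum reads per allele.
#' @return Filtered tibble.
#' @export
het_support_filter <- function(calls, min_reads = 3) {
  if (nrow(calls) == 0) return(calls)
  out <- calls %>% mutate(
    gt = if_else(.data$gt == "het" &
                   (.data$ad_ref < min_reads | .data$ad_alt < min_reads),
                 "missing", .data$gt))
  keep <- out %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(any_var = any(.data$gt %in% c("het", "hom_alt")),
              .groups = "drop") %>%
    filter(.data$any_var)
  out %>% semi_join(keep, by = c("chrom", "pos"))
}

#' Classify surviving variants into candidate mutation classes
#'
#' Point mutation: ancestor homozygous-reference and exactly one offspring
#' heterozygous. LOH: ancestor heterozygous and at least one offspring
#' homozygous (either allele) — excluded from rate estimation, as gene
#' conversion rather than new mutation. Indels are flagged, and those
#' overlapping the repeat mask are marked `likely_false` (simple sequence
#' repeats and transposable elements generate alignment artifacts). The
#' mutation spectrum label (pyrimidine-first complementary pair, e.g.
#' `C:G>T:A`) is assigned to point mutations only.
#'
#' @param calls Filtered site-call tibble.
#' @param ancestor Ancestor sample id.
#' @param repeat_mask Optional tibble `chrom, start, end` (0-based
#'   half-open) of repeat regions.
#' @return Tibble of candidates: `sample, chrom, pos, ref, alt, class,
#'   spectrum, likely_false`.
#' @export
classify_candidates <- function(calls, ancestor, repeat_mask = NULL) {
  cand_cols <- function() tibble(
    sample = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), class = character(),
    spectrum = character(), likely_false = logical())
  if (nrow(calls) == 0) return(cand_cols())
  if (!ancestor %in% calls$sample) abort("ancestor sample missing from calls")

  anc <- calls %>% filter(.data$sample == ancestor) %>%
    select("chrom", "pos", anc_gt = "gt")
  off <- calls %>% filter(.data$sample != ancestor) %>%
    left_join(anc, by = c("chrom", "pos"))
  is_indel <- nchar(off$ref) != 1L | nchar(off$alt) != 1L

  point <- off %>%
    filter(!is_indel, .data$anc_gt == "hom_ref", .data$gt == "het") %>%
    group_by(.data$chrom, .data$pos) %>%
    filter(n() == 1L) %>%
    ungroup() %>%
    mutate(class = "point",
           spectrum = spectrum_label(.data$ref, .data$alt))
  loh <- off %>%
    filter(!is_indel, .data$anc_gt == "het",
           .data$gt %in% c("hom_ref", "hom_alt")) %>%
    mutate(class = "LOH", spectrum = NA_character_)
  indel <- off %>%
    filter(is_indel, .data$gt %in% c("het", "hom_alt")) %>%
    mutate(class = "indel", spectrum = NA_character_)

  out <- bind_rows(point, loh, indel) %>%
    select("sample", "chrom", "pos", "ref", "alt", "class", "spectrum")
  if (nrow(out) == 0) return(cand_cols())
  out$likely_false <- FALSE
  if (!is.null(repeat_mask) && nrow(repeat_mask) > 0) {
    in_rep <- vapply(seq_len(nrow(out)), function(i) {
      any(repeat_mask$chrom == out$chrom[i] &
            repeat_mask$start < out$pos[i] & out$pos[i] <= repeat_mask$end)
    }, logical(1))
    out$likely_false <- out$class == "indel" & in_rep
  }
  out %>% arrange(.data$chrom, .data$pos, .data$sample)
}

# pyrimidine-first complementary-pair label, e.g. G->A  =>  "C:G>T:A"
spectrum_label <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp[ref], ref)
  a <- ifelse(pur, comp[alt], alt)
  paste0(r, ":", comp[r], ">", a, ":", comp[a])
}

#' Run the full de novo candidate filtering cascade
#'
#' Applies the filters in pipeline order: read support, callable-band
#' restriction, hard site filters, variant-cluster removal, cross-sample
#' sharing, heterozygote allele support, then classification. Per-sample
#' records at positions outside that sample's callable mask are set to
#' missing before site filters run, and a point candidate additionally
#' requires the ancestor callable (hom-ref with data) at the site.
#'
#' @param calls Site-call tibble (multi-sample).
#' @param depth Named list of per-position depth vectors, or a precomputed
#'   callable-mask tibble.
#' @param ancestor Ancestor sample id.
#' @param repeat_mask Optional repeat-region tibble.
#' @param min_depth,max_depth Callable band (inclusive).
#' @param cluster_window,cluster_min Variant-cluster definition.
#' @param max_shared Cross-sample carrier limit.
#' @param min_support Minimum reads per allele for het records.
#' @param include_ancestor Count ancestor in the sharing filter.
#' @return List of class `ma_pipeline`: `candidates`, `masks`, and
#'   `report` (tibble of sites surviving each stage).
#' @export
run_ma_pipeline <- function(calls, depth, ancestor = "ANC",
                            repeat_mask = NULL,
                            min_depth = 9, max_depth = 75,
                            cluster_window = 50, cluster_min = 3,
                            max_shared = 2, min_support = 3,
                            include_ancestor = TRUE) {
  masks <- if (inherits(depth, "callable_mask")) {
    depth
  } else {
    compute_callable(depth, min_depth, max_depth)
  }
  n_sites <- function(x) nrow(distinct(x, .data$chrom, .data$pos))
  report <- list(tibble(stage = "input", sites = n_sites(calls)))

  step1 <- filter_read_support(calls)
  report <- c(report, list(tibble(stage = "read_support", sites = n_sites(step1))))

  # callable restriction per sample
  key <- paste(step1$sample, step1$chrom)
  step2 <- step1 %>%
    group_by(.data$sample, .data$chrom) %>%
    mutate(callable = in_mask(masks, .data$sample[1], .data$chrom[1], .data$pos)) %>%
    ungroup() %>%
    mutate(gt = if_else(.data$callable, .data$gt, "missing")) %>%
    select(-"callable")
  keep <- step2 %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(any_var = any(.data$gt %in% c("het", "hom_alt")), .groups = "drop") %>%
    filter(.data$any_var)
  step2 <- step2 %>% semi_join(keep, by = c("chrom", "pos"))
  report <- c(report, list(tibble(stage = "callable", sites = n_sites(step2))))

  step3 <- hard_filter_sites(step2)
  report <- c(report, list(tibble(stage = "hard_filter", sites = n_sites(step3))))

  step4 <- annotate_clusters(step3, cluster_window, cluster_min) %>%
    filter(!.data$cluster_flag) %>% select(-"cluster_flag")
  report <- c(report, list(tibble(stage = "cluster_removal", sites = n_sites(step4))))

  step5 <- cross_sample_filter(step4, max_shared,
                               include_ancestor = include_ancestor,
                               ancestor = ancestor)
  report <- c(report, list(tibble(stage = "cross_sample", sites = n_sites(step5))))

  step6 <- het_support_filter(step5, min_support)
  report <- c(report, list(tibble(stage = "het_support", sites = n_sites(step6))))

  cands <- classify_candidates(step6, ancestor, repeat_mask)
  report <- c(report, list(tibble(stage = "candidates", sites = nrow(cands))))

  structure(list(candidates = cands, masks = masks,
                 report = bind_rows(report)),
            class = "ma_pipeline")
}

#' @export
print.ma_pipeline <- function(x, ...) {
  cat("MA filtering pipeline\n")
  print(x$report)
  cat("\nCandidates by class:\n")
  print(count(x$candidates, .data$class))
  invisible(x)
}
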