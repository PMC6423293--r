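#' Configuration for a synthetic mutation-accumulation experiment
#'
#' Bundles every knob of the MA-experiment generator: one diploid ancestor,
#' `n_lines_per_treatment` offspring lines per treatment propagated as single
#' descendants for `generations` generations, short-read-like depths and
#' allele counts at every emitted variant site, plus the nuisance signal
#' (ancestral heterozygous loci, loss of heterozygosity, shared and clustered
#' artifact sites, indel artifacts inside a simple-repeat mask, per-base
#' sequencing error) that the downstream filtering cascade exists to remove.
#'
#' Depth is negative-binomial with mean `mean_depth` and size
#' `depth_dispersion` (variance `m + m^2/size`); `depth_dispersion = 0`
#' requests constant depth, which also makes every position callable.
#' `true_mu` is a named vector of per-site per-generation mutation rates, one
#' per treatment. `n_ancestor_hets = NULL` scales the ancestral heterozygous
#' loci with genome length at 2.4e-4 per bp (the density implied by ~30,000
#' hets over a ~126 Mb callable genome).
#'
#' @param genome_length Genome size in bp (single chromosome `"chr1"`).
#' @param n_lines_per_treatment Offspring lines per treatment.
#' @param treatments Character vector of treatment labels.
#' @param true_mu Named per-treatment true mutation rate
#'   (mutations per site per generation); names must cover `treatments`.
#' @param generations Number of single-descendant generations.
#' @param mean_depth Mean sequencing depth per sample.
#' @param depth_dispersion Negative-binomial size; 0 = constant depth.
#' @param seq_error_rate Per-base per-read sequencing error probability.
#' @param n_ancestor_hets Count of ancestral heterozygous loci, or `NULL`
#'   to scale with genome length.
#' @param loh_rate Per-het-site per-line probability of loss of
#'   heterozygosity.
#' @param artifact_site_rate Per-bp rate of shared/clustered artifact sites.
#' @param indel_artifact_rate Per-bp rate of false-positive indel sites,
#'   placed preferentially inside the simulated repeat mask.
#' @param repeat_fraction Fraction of the genome covered by the simulated
#'   simple-repeat mask.
#' @param seed Integer seed; identical seed and config give identical output.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 1e4, seed = 1)
sim_config <- function(genome_length = 1e6,
                       n_lines_per_treatment = 5,
                       treatments = c("indoor", "outdoor-noUV", "outdoor-UV"),
                       true_mu = c("indoor" = 0,
                                   "outdoor-noUV" = 7.92e-11,
                                   "outdoor-UV" = 2.38e-10),
                       generations = 20,
                       mean_depth = 28,
                       depth_dispersion = 10,
                       seq_error_rate = 1e-3,
                       n_ancestor_hets = NULL,
                       loh_rate = 1e-3,
                       artifact_site_rate = 5e-6,
                       indel_artifact_rate = 1e-6,
                       repeat_fraction = 0.05,
                       seed = 1L) {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    abort("`genome_length` must be a positive number of bp.")
  }
  if (is.null(names(true_mu)) || !all(treatments %in% names(true_mu))) {
    abort("`true_mu` must be named and cover every treatment label.")
  }
  rates <- c(true_mu, seq_error_rate, loh_rate, artifact_site_rate,
             indel_artifact_rate, repeat_fraction)
  if (any(rates < 0 | rates > 1)) {
    abort("All rates must lie in [0, 1].")
  }
  if (generations < 1) abort("`generations` must be >= 1.")
  if (is.null(n_ancestor_hets)) {
    n_ancestor_hets <- round(2.4e-4 * genome_length)
  }
  structure(list(
    genome_length = as.integer(genome_length),
    n_lines_per_treatment = as.integer(n_lines_per_treatment),
    treatments = treatments,
    true_mu = true_mu[treatments],
    generations = as.integer(generations),
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    seq_error_rate = seq_error_rate,
    n_ancestor_hets = as.integer(n_ancestor_hets),
    loh_rate = loh_rate,
    artifact_site_rate = artifact_site_rate,
    indel_artifact_rate = indel_artifact_rate,
    repeat_fraction = repeat_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# depth vector for one sample; size = 0 means constant depth
draw_depth <- function(L, mean_depth, dispersion) {
  if (dispersion <= 0) {
    rep(as.integer(round(mean_depth)), L)
  } else {
    rnbinom(L, mu = mean_depth, size = dispersion)
  }
}

# deterministic per-line seed stream: adding a line never perturbs others
line_seed <- function(seed, i) (as.integer(seed) + 7919L * as.integer(i)) %% .Machine$integer.max

# simple genotype caller applied to simulated allele depths
call_gt <- function(ad_ref, ad_alt) {
  dp <- ad_ref + ad_alt
  f <- ifelse(dp > 0, ad_alt / dp, 0)
  case_when(
    dp == 0 ~ "missing",
    ad_alt < 2 | f < 0.15 ~ "hom_ref",
    ad_ref < 2 & f > 0.85 ~ "hom_alt",
    TRUE ~ "het"
  )
}

#' Simulate a mutation-accumulation experiment with known truth
#'
#' Generates a multi-sample variant table (ancestor plus offspring lines),
#' per-sample depth profiles, callable masks and a truth record. Per line,
#' true de novo mutations are drawn `Poisson(mu * L_callable * g)` and placed
#' uniformly over that line's callable positions; each is heterozygous in
#' exactly one offspring with allele depths `Binomial(depth, 0.5)`.
#' Ancestral heterozygous loci are carried by every sample except where a
#' loss-of-heterozygosity event is simulated; artifact sites appear in three
#' or more samples and/or in dense clusters; indel artifacts fall mostly in
#' the repeat mask; sequencing error produces spurious low-support records.
#'
#' @param config A [sim_config()].
#' @return A list of class `ma_sim` with elements
#'   `calls` (tibble, one row per site x sample), `samples` (sample
#'   metadata), `depth` (named list of per-position integer depth vectors),
#'   `masks` (callable-mask tibble from [compute_callable()]),
#'   `truth` (class `sim_truth`: `true_mutations`, `ancestor_hets`,
#'   `loh_events`, `spiked`, `repeat_mask`), and `config`.
#' @export
#' @examples
#' sim <- simulate_ma_experiment(sim_config(genome_length = 5e3, seed = 42))
#' dplyr::count(sim$calls, gt)
simulate_ma_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  g <- config$generations
  n_tr <- length(config$treatments)
  n_off <- n_tr * config$n_lines_per_treatment

  samples <- tibble(
    sample = c("ANC", sprintf("L%02d", seq_len(n_off))),
    treatment = c(NA_character_,
                  rep(config$treatments, each = config$n_lines_per_treatment)),
    is_ancestor = c(TRUE, rep(FALSE, n_off))
  )

  ## master stream: shared genomic features
  set.seed(config$seed)
  ref_base <- function(n) sample(BASES, n, replace = TRUE)
  alt_base <- function(ref) {
    unname(vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                  character(1)))
  }

  # repeat mask: contiguous blocks totalling repeat_fraction of the genome
  rep_len <- round(config$repeat_fraction * L)
  repeat_mask <- if (rep_len >= 200 && L >= 1000) {
    n_blk <- max(1L, rep_len %/% 200L)
    starts <- sort(sample.int(L - 200L, n_blk))
    tibble(chrom = "chr1", start = starts - 1L,
           end = pmin(starts - 1L + 200L, L)) %>%
      distinct(.data$start, .keep_all = TRUE)
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }

  anc_het_pos <- sort(sample.int(L, min(config$n_ancestor_hets, L)))
  anc_het <- tibble(chrom = "chr1", pos = anc_het_pos,
                    ref = ref_base(length(anc_het_pos)))
  anc_het$alt <- alt_base(anc_het$ref)

  # artifact sites: half shared across >=3 samples, half in clusters of 3
  n_art <- rpois(1, config$artifact_site_rate * L)
  n_shared <- ceiling(n_art / 2)
  n_clust_groups <- max(0L, floor((n_art - n_shared) / 1L))
  shared_pos <- if (n_shared > 0) sample.int(L, n_shared) else integer()
  clust_pos <- integer()
  if (n_clust_groups > 0) {
    anchors <- sample.int(max(1L, L - 60L), n_clust_groups)
    clust_pos <- as.integer(unlist(lapply(anchors, function(a) {
      a + sort(sample.int(49L, 3L))
    })))
  }
  n_indel <- rpois(1, config$indel_artifact_rate * L)
  indel_pos <- integer()
  if (n_indel > 0) {
    # 80% of indel artifacts inside the repeat mask when one exists
    in_rep <- nrow(repeat_mask) > 0 & runif(n_indel) < 0.8
    pick_rep <- function() {
      i <- sample.int(nrow(repeat_mask), 1L)
      repeat_mask$start[i] + sample.int(repeat_mask$end[i] - repeat_mask$start[i], 1L)
    }
    indel_pos <- vapply(seq_len(n_indel), function(i) {
      if (in_rep[i]) pick_rep() else sample.int(L, 1L)
    }, integer(1))
  }

  ## per-sample streams: depths, true mutations, LOH
  all_samples <- samples$sample
  depth <- vector("list", length(all_samples))
  names(depth) <- all_samples
  true_mut <- vector("list", length(all_samples))
  loh <- vector("list", length(all_samples))

  for (i in seq_along(all_samples)) {
    sm <- all_samples[i]
    set.seed(line_seed(config$seed, i))
    dp <- draw_depth(L, config$mean_depth, config$depth_dispersion)
    depth[[i]] <- dp
    if (samples$is_ancestor[i]) next
    callable <- which(dp >= 9L & dp <= 75L)
    mu <- config$true_mu[[samples$treatment[i]]]
    k <- rpois(1, mu * length(callable) * g)
    if (k > 0) {
      pos <- sort(sample(callable, min(k, length(callable))))
      ref <- ref_base(length(pos))
      true_mut[[i]] <- tibble(sample = sm, chrom = "chr1", pos = pos,
                              ref = ref, alt = alt_base(ref))
    }
    if (config$loh_rate > 0 && nrow(anc_het) > 0) {
      hit <- which(runif(nrow(anc_het)) < config$loh_rate)
      if (length(hit) > 0) {
        loh[[i]] <- tibble(sample = sm, chrom = "chr1",
                           pos = anc_het$pos[hit],
                           to = sample(c("hom_ref", "hom_alt"),
                                       length(hit), replace = TRUE))
      }
    }
  }
  true_mut <- bind_rows(true_mut)
  loh <- bind_rows(loh)
  if (nrow(true_mut) == 0) {
    true_mut <- tibble(sample = character(), chrom = character(),
                       pos = integer(), ref = character(), alt = character())
  }
  if (nrow(loh) == 0) {
    loh <- tibble(sample = character(), chrom = character(),
                  pos = integer(), to = character())
  }

  ## error-read sites (per sample; emitted when >=2 error reads pile up)
  set.seed(line_seed(config$seed, length(all_samples) + 1L))
  err_sites <- list()
  if (config$seq_error_rate > 0) {
    for (i in seq_along(all_samples)) {
      dp <- depth[[i]]
      err <- rbinom(L, dp, config$seq_error_rate)
      at <- which(err >= 2L)
      if (length(at) > 0) {
        err_sites[[all_samples[i]]] <-
          tibble(sample = all_samples[i], pos = at, n_err = err[at])
      }
    }
  }
  err_sites <- bind_rows(err_sites)

  ## assemble the site catalogue (position, ref, alt, origin)
  site_cat <- bind_rows(
    anc_het %>% mutate(origin = "anc_het"),
    true_mut %>% select("chrom", "pos", "ref", "alt") %>%
      mutate(origin = "true"),
    {
      ap <- unique(c(shared_pos, clust_pos))
      r <- ref_base(length(ap))
      tibble(chrom = "chr1", pos = as.integer(ap), ref = r,
             alt = alt_base(r), origin = "artifact")
    },
    {
      r <- ref_base(length(indel_pos))
      tibble(chrom = "chr1", pos = as.integer(indel_pos), ref = r,
             alt = paste0(r, "A"), origin = "indel")
    },
    if (nrow(err_sites) > 0) {
      ep <- sort(unique(err_sites$pos))
      r <- ref_base(length(ep))
      tibble(chrom = "chr1", pos = ep, ref = r, alt = alt_base(r),
             origin = "error")
    }
  )
  # collisions: first origin wins, priority anc_het > true > artifact > indel > error
  site_cat <- site_cat %>%
    mutate(prio = match(.data$origin,
                        c("anc_het", "true", "artifact", "indel", "error"))) %>%
    arrange(.data$pos, .data$prio) %>%
    distinct(.data$pos, .keep_all = TRUE) %>%
    select(-"prio")

  calls <- build_calls(site_cat, samples, depth, true_mut, loh, err_sites,
                       shared_pos, clust_pos, config)

  truth <- structure(list(
    true_mutations = true_mut,
    ancestor_hets = anc_het,
    loh_events = loh,
    spiked = tibble(sample = character(), chrom = character(),
                    pos = integer(), target_af = numeric()),
    repeat_mask = repeat_mask
  ), class = "sim_truth")

  masks <- compute_callable(depth)

  structure(list(calls = calls, samples = samples, depth = depth,
                 masks = masks, truth = truth, config = config),
            class = "ma_sim")
}

# one row per (site, sample), VCF-like long layout
build_calls <- function(site_cat, samples, depth, true_mut, loh, err_sites,
                        shared_pos, clust_pos, config) {
  n_site <- nrow(site_cat)
  if (n_site == 0) {
    return(empty_calls())
  }
  sm <- samples$sample
  grid <- tidyr::expand_grid(site = seq_len(n_site), sample = sm) %>%
    mutate(pos = site_cat$pos[.data$site],
           ref = site_cat$ref[.data$site],
           alt = site_cat$alt[.data$site],
           origin = site_cat$origin[.data$site])
  dp_at <- function(sample, pos) {
    vapply(seq_along(sample),
           function(i) depth[[sample[i]]][pos[i]], numeric(1))
  }
  set.seed(line_seed(config$seed, length(sm) + 2L))
  grid$dp <- as.integer(dp_at(grid$sample, grid$pos))

  # carrier status per record
  grid$is_true <- FALSE
  if (nrow(true_mut) > 0) {
    key <- paste(grid$sample, grid$pos)
    grid$is_true <- key %in% paste(true_mut$sample, true_mut$pos)
  }
  grid$is_anc_het_site <- grid$origin == "anc_het"
  grid$loh_to <- NA_character_
  if (nrow(loh) > 0) {
    m <- match(paste(grid$sample, grid$pos), paste(loh$sample, loh$pos))
    grid$loh_to <- loh$to[m]
  }
  # artifact carriers: >=3 random samples per artifact site (deterministic
  # under the seed set above)
  art_pos <- unique(c(shared_pos, clust_pos))
  grid$is_art_carrier <- FALSE
  if (length(art_pos) > 0) {
    carriers <- lapply(art_pos, function(p) {
      sample(sm, sample(3:min(6, length(sm)), 1L))
    })
    names(carriers) <- as.character(art_pos)
    idx <- grid$origin == "artifact"
    grid$is_art_carrier[idx] <- mapply(
      function(s, p) s %in% carriers[[as.character(p)]],
      grid$sample[idx], grid$pos[idx])
  }
  # indel artifacts: LOH-like, carried by 1-2 samples
  grid$is_indel_carrier <- FALSE
  ind_pos <- unique(grid$pos[grid$origin == "indel"])
  if (length(ind_pos) > 0) {
    icar <- lapply(ind_pos, function(p) sample(sm, sample(1:2, 1L)))
    names(icar) <- as.character(ind_pos)
    idx <- grid$origin == "indel"
    grid$is_indel_carrier[idx] <- mapply(
      function(s, p) s %in% icar[[as.character(p)]],
      grid$sample[idx], grid$pos[idx])
  }

  e <- config$seq_error_rate
  dp <- grid$dp
  het <- grid$is_true |
    (grid$is_anc_het_site & is.na(grid$loh_to)) |
    grid$is_art_carrier | grid$is_indel_carrier
  ad_alt <- integer(nrow(grid))
  ad_alt[het] <- rbinom(sum(het), dp[het], 0.5)
  hom_alt <- grid$is_anc_het_site & !is.na(grid$loh_to) &
    grid$loh_to == "hom_alt"
  ad_alt[hom_alt] <- dp[hom_alt] - rbinom(sum(hom_alt), dp[hom_alt], e)
  rest <- !het & !hom_alt
  ad_alt[rest] <- if (e > 0) rbinom(sum(rest), dp[rest], e) else 0L
  # overlay recorded error pile-ups so truth bookkeeping matches emission
  if (nrow(err_sites) > 0) {
    m <- match(paste(grid$sample, grid$pos),
               paste(err_sites$sample, err_sites$pos))
    hit <- !is.na(m) & rest
    ad_alt[hit] <- pmin(dp[hit], as.integer(err_sites$n_err[m[hit]]))
  }
  ad_alt <- pmin(ad_alt, dp)
  grid$ad_alt <- as.integer(ad_alt)
  grid$ad_ref <- as.integer(dp - ad_alt)
  grid$gt <- call_gt(grid$ad_ref, grid$ad_alt)
  grid$proper_pair_fraction <- 1.0
  grid$median_insert <- 350L

  # site-level annotations: clean origins get confident QUAL/QD, noisy
  # origins get values straddling the hard-filter thresholds
  site_ann <- grid %>%
    group_by(.data$pos) %>%
    summarise(dp_site = sum(.data$dp), origin = .data$origin[1],
              .groups = "drop")
  clean <- site_ann$origin %in% c("anc_het", "true")
  nsite <- nrow(site_ann)
  site_ann$qual <- ifelse(clean, runif(nsite, 200, 1000), runif(nsite, 20, 80))
  site_ann$qd <- ifelse(clean, runif(nsite, 15, 30), runif(nsite, 2, 15))
  site_ann$mq0 <- ifelse(clean, 0L, rpois(nsite, 1))

  grid %>%
    left_join(site_ann %>% select("pos", "dp_site", "qual", "qd", "mq0"),
              by = "pos") %>%
    mutate(chrom = "chr1") %>%
    select("chrom", "pos", "ref", "alt", "qual", "qd", "mq0", "dp_site",
           "sample", "gt", "ad_ref", "ad_alt", "dp",
           "proper_pair_fraction", "median_insert") %>%
    arrange(.data$pos, .data$sample)
}

empty_calls <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), qual = numeric(), qd = numeric(),
         mq0 = integer(), dp_site = integer(), sample = character(),
         gt = character(), ad_ref = integer(), ad_alt = integer(),
         dp = integer(), proper_pair_fraction = numeric(),
         median_insert = integer())
}

#' Inject synthetic heterozygous variants into a call table
#'
#' Places `n` new non-reference variant records uniformly over the callable
#' regions of randomly chosen samples, with target alternate-allele fraction
#' drawn from a normal distribution truncated to (0, 1). The spiked allele
#' depth is `round(dp * af)`, so at depth >= 9 with fraction 0.5 both alleles
#' are guaranteed at least three supporting reads. Positions colliding with
#' existing variant sites are re-drawn. Used to measure pipeline recall
#' (spike-in false-negative estimation).
#'
#' @param calls Site-call tibble (as emitted by [simulate_ma_experiment()]).
#' @param masks Callable-mask tibble from [compute_callable()].
#' @param n Number of variants to inject.
#' @param freq_mean,freq_sd Mean and SD of the target allele fraction.
#' @param seed Integer seed.
#' @param depth Optional named list of per-position depth vectors; when
#'   absent, depths are drawn negative-binomially and truncated to the
#'   callable band.
#' @param samples Samples eligible to receive spikes; defaults to all
#'   samples present in `masks`.
#' @param min_spacing Minimum distance in bp from any existing variant or
#'   other spike (0 disables). At study-like spike densities clustering is
#'   negligible; set this above the cluster window when spiking densely,
#'   otherwise co-spiked clusters are legitimately removed downstream.
#' @return List with `calls` (augmented table) and `truth`
#'   (class `sim_truth` with the `spiked` slot filled).
#' @export
spike_in <- function(calls, masks, n = 1000, freq_mean = 0.5, freq_sd = 0.1,
                     seed = 1L, depth = NULL, samples = NULL,
                     min_spacing = 0) {
  if (n == 0) {
    return(list(calls = calls,
                truth = structure(list(spiked = tibble(
                  sample = character(), chrom = character(),
                  pos = integer(), target_af = numeric())),
                  class = "sim_truth")))
  }
  stopifnot(n >= 1)
  if (is.null(samples)) samples <- unique(masks$sample)
  set.seed(seed)
  msk <- masks %>% filter(.data$sample %in% .env$samples)
  msk$len <- msk$end - msk$start
  total <- sum(msk$len)
  if (total < n) abort("callable space smaller than the number of spikes")

  taken <- calls %>% distinct(.data$chrom, .data$pos)
  clear <- function(chrom, pos) {
    occ <- c(taken$pos[taken$chrom == chrom])
    if (min_spacing > 0) {
      length(occ) == 0 || min(abs(occ - pos)) > min_spacing
    } else {
      !any(occ == pos)
    }
  }
  picks <- vector("list", n)
  for (j in seq_len(n)) {
    repeat {
      i <- sample.int(nrow(msk), 1L, prob = msk$len)
      pos <- msk$start[i] + sample.int(msk$len[i], 1L)  # 1-based
      if (clear(msk$chrom[i], pos)) break
    }
    taken <- bind_rows(taken, tibble(chrom = msk$chrom[i], pos = pos))
    picks[[j]] <- list(sample = msk$sample[i], chrom = msk$chrom[i],
                       pos = pos)
  }
  spiked <- bind_rows(lapply(picks, as_tibble))
  af <- rnorm(n, freq_mean, freq_sd)
  af <- pmin(pmax(af, 1e-6), 1 - 1e-6)
  spiked$target_af <- af
  spiked$ref <- sample(BASES, n, replace = TRUE)
  spiked$alt <- unname(vapply(spiked$ref,
                              function(b) sample(setdiff(BASES, b), 1L),
                              character(1)))

  all_samples <- unique(c(calls$sample, masks$sample))
  dp_for <- function(sm, pos) {
    if (!is.null(depth) && sm %in% names(depth)) {
      as.integer(depth[[sm]][pos])
    } else {
      d <- 0L
      while (d < 9L || d > 75L) d <- rnbinom(1L, mu = 28, size = 10)
      as.integer(d)
    }
  }
  rows <- purrr::map_dfr(seq_len(n), function(j) {
    s <- spiked[j, ]
    purrr::map_dfr(all_samples, function(sm) {
      dp <- dp_for(sm, s$pos)
      if (sm == s$sample) {
        aa <- as.integer(round(dp * s$target_af))
        aa <- max(0L, min(dp, aa))
      } else {
        aa <- 0L
      }
      tibble(chrom = s$chrom, pos = as.integer(s$pos), ref = s$ref,
             alt = s$alt, qual = 500, qd = 25, mq0 = 0L,
             dp_site = NA_integer_, sample = sm,
             gt = call_gt(dp - aa, aa), ad_ref = as.integer(dp - aa),
             ad_alt = aa, dp = dp, proper_pair_fraction = 1.0,
             median_insert = 350L)
    })
  })
  rows <- rows %>%
    group_by(.data$chrom, .data$pos) %>%
    mutate(dp_site = sum(.data$dp)) %>%
    ungroup()
  out <- bind_rows(calls, rows) %>% arrange(.data$pos, .data$sample)
  truth <- structure(list(
    spiked = spiked %>% select("sample", "chrom", "pos", "target_af")
  ), class = "sim_truth")
  list(calls = out, truth = truth)
}

#' Simulate an infinite-sites coalescent sample
#'
#' Standard neutral coalescent for a non-recombining locus: exponential
#' waiting times between coalescences (rate k(k-1)/2 with k active
#' lineages), mutations dropped as Poisson(theta/2 x total branch length)
#' and assigned to branches proportionally to length, each creating one
#' segregating site under the infinite-sites model.
#'
#' @param n_haplotypes Number of sampled haplotypes (>= 2).
#' @param theta Population mutation parameter (4 Ne mu per locus).
#' @param seed Integer seed.
#' @return A list of class `coalescent_sample`: `n_haplotypes`, `theta`,
#'   `haplotypes` (0/1 matrix, haplotypes x segregating sites) and
#'   `positions` (relative coordinates in \[0,1)).
#' @export
#' @examples
#' cs <- simulate_coalescent(10, theta = 1, seed = 7)
#' ncol(cs$haplotypes)  # number of segregating sites
simulate_coalescent <- function(n_haplotypes, theta, seed = NULL) {
  if (n_haplotypes < 2) abort("`n_haplotypes` must be >= 2.")
  if (theta <= 0) abort("`theta` must be > 0.")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_haplotypes)
  # active lineages as leaf sets; record (leafset, duration) segments
  active <- lapply(seq_len(n), identity)
  seg_sets <- list()
  seg_len <- numeric(0)
  k <- n
  while (k > 1) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    for (l in active) {
      seg_sets[[length(seg_sets) + 1L]] <- l
      seg_len <- c(seg_len, t_k)
    }
    pair <- sample.int(k, 2L)
    merged <- c(active[[pair[1]]], active[[pair[2]]])
    active <- c(active[-pair], list(merged))
    k <- k - 1L
  }
  total_len <- sum(seg_len)
  S <- rpois(1, theta / 2 * total_len)
  if (S == 0) {
    hap <- matrix(0L, nrow = n, ncol = 0)
    pos <- numeric(0)
  } else {
    br <- sample.int(length(seg_len), S, replace = TRUE, prob = seg_len)
    hap <- matrix(0L, nrow = n, ncol = S)
    for (j in seq_len(S)) hap[seg_sets[[br[j]]], j] <- 1L
    pos <- runif(S)
    ord <- order(pos)
    hap <- hap[, ord, drop = FALSE]
    pos <- pos[ord]
  }
  structure(list(n_haplotypes = n, theta = theta,
                 haplotypes = hap, positions = pos),
            class = "coalescent_sample")
}
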