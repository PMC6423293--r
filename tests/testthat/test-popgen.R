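test_that("pi counts pairwise differences per site", {
  # two haplotypes differing at 1 of 100 sites
  g <- genotype_matrix(matrix(c(0, 1), nrow = 2, ncol = 1),
                       positions = 5, callable_length = 100, ploidy = 1)
  expect_equal(nucleotide_diversity(g), 0.01)
  mono <- genotype_matrix(matrix(0, 3, 4), ploidy = 1)
  expect_equal(nucleotide_diversity(mono), 0)
  # doubling callable length halves pi
  g2 <- genotype_matrix(matrix(c(0, 1), 2, 1), positions = 5,
                        callable_length = 200, ploidy = 1)
  expect_equal(nucleotide_diversity(g2), nucleotide_diversity(g) / 2)
})

test_that("pi is invariant under sample permutation and missing-aware", {
  set.seed(2)
  d <- matrix(rbinom(60, 2, 0.3), nrow = 6)
  d[sample(length(d), 5)] <- NA
  g <- genotype_matrix(d, ploidy = 2)
  gp <- genotype_matrix(d[sample(6), ], ploidy = 2)
  expect_equal(nucleotide_diversity(g), nucleotide_diversity(gp))
})

test_that("cohort depth filter is strict at both bounds", {
  calls <- dplyr::bind_rows(
    make_site(1, c(L01 = "het")) |> dplyr::mutate(dp_site = 510L),
    make_site(2, c(L01 = "het")) |> dplyr::mutate(dp_site = 2000L),
    make_site(3, c(L01 = "het")) |> dplyr::mutate(dp_site = 10200L)
  )
  out <- cohort_depth_filter(calls)
  expect_equal(out$pos, 2L)
  # brute-force survivor scan on a random table
  set.seed(77)
  tbl <- make_site(1, c(L01 = "het"))[rep(1, 200), ] |>
    dplyr::mutate(pos = 1:200,
                  dp_site = as.integer(runif(200, 0, 12000)))
  out2 <- cohort_depth_filter(tbl)
  expect_setequal(out2$pos,
                  tbl$pos[tbl$dp_site > 510 & tbl$dp_site < 10200])
  # organelle-style mask exclusion
  msk <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  out3 <- cohort_depth_filter(tbl, exclude_mask = msk)
  expect_true(all(out3$pos > 100))
})

test_that("Tajima's D matches an independent closed-form computation", {
  # n = 4, S = 3, mean pairwise differences 1.667; constants written out
  # from the standard definitions, independently of the implementation
  n <- 4; S <- 3; pt <- 1.667
  a1 <- 1 + 1/2 + 1/3
  a2 <- 1 + 1/4 + 1/9
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1/a1; c2 <- b2 - (n + 2)/(a1 * n) + a2/a1^2
  e1 <- c1/a1; e2 <- c2/(a1^2 + a2)
  want <- (pt - S/a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(S, n, pt), want)
  expect_warning(d0 <- tajimas_d(0, 10, 0), "undefined")
  expect_true(is.na(d0))
  expect_error(tajimas_d(3, 3, 1), "n >= 4")
})

test_that("Tajima's D averages near zero for neutral coalescent samples", {
  set.seed(19)
  d <- vapply(1:2000, function(i) {
    cs <- simulate_coalescent(10, theta = 3)
    st <- diversity_stats(as_genotype_matrix(cs, ploidy = 1))
    st$tajimas_d
  }, numeric(1))
  d <- d[!is.na(d)]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.05)
})

test_that("Hudson Fst hits both trivial endpoints and the per-site oracle", {
  fixed_a <- genotype_matrix(matrix(2, 3, 5), ploidy = 2)
  fixed_b <- genotype_matrix(matrix(0, 3, 5), ploidy = 2)
  expect_equal(pairwise_fst(fixed_a, fixed_b), 1)
  # exchangeable populations: random label splits of one pool average ~0
  set.seed(4)
  pool <- matrix(rbinom(16 * 30, 2, runif(30, 0.2, 0.8)), nrow = 16,
                 byrow = TRUE)
  fsts <- vapply(1:200, function(i) {
    idx <- sample(16, 8)
    pairwise_fst(genotype_matrix(pool[idx, ], ploidy = 2),
                 genotype_matrix(pool[-idx, ], ploidy = 2))
  }, numeric(1))
  expect_lt(abs(mean(fsts)), 3 * sd(fsts) / sqrt(200) + 0.01)
  # ratio-of-averages against a hand computation on random demes
  da <- matrix(rbinom(50, 2, 0.2), 5)
  db <- matrix(rbinom(50, 2, 0.6), 5)
  ga <- genotype_matrix(da, ploidy = 2); gb <- genotype_matrix(db, ploidy = 2)
  p1 <- colMeans(da) / 2; p2 <- colMeans(db) / 2
  n1 <- 10; n2 <- 10
  hw <- (2 * p1 * (1 - p1) * n1/(n1 - 1) + 2 * p2 * (1 - p2) * n2/(n2 - 1)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(pairwise_fst(ga, gb), 1 - mean(hw) / mean(hb))
  expect_error(pairwise_fst(fixed_a, fixed_a), "undefined")
})

test_that("LD r2 is dosage correlation squared with MAF gating", {
  # perfectly co-varying dosages
  d <- cbind(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2))
  g <- genotype_matrix(d, positions = c(100, 300), ploidy = 2)
  pr <- ld_r2(g, maf_min = 0.05)
  expect_equal(pr$r2, 1)
  expect_equal(pr$distance, 200)
  # a MAF 0.04 site is excluded ("greater than 0.05" is strict, 0.04 < 0.05)
  d2 <- cbind(c(rep(0, 24), 1), rbinom(25, 2, 0.5))
  g2 <- genotype_matrix(d2, positions = c(10, 50), ploidy = 2)
  expect_equal(nrow(ld_r2(g2, maf_min = 0.05)), 0)
  # independent sites: E[r2] ~ 1/n_samples
  set.seed(31)
  n <- 100
  d3 <- matrix(rbinom(n * 40, 2, 0.5), nrow = n)
  g3 <- genotype_matrix(d3, positions = seq_len(40) * 10, ploidy = 2)
  pr3 <- ld_r2(g3, maf_min = 0.05)
  expect_lt(abs(mean(pr3$r2) - 1 / n), 3 / n)
})

test_that("LD binning matches brute-force grouping", {
  pairs <- tibble::tibble(pos1 = 0, pos2 = 0,
                          distance = c(150, 150, 150), r2 = c(0.2, 0.4, 0.6))
  b <- bin_ld(pairs)
  expect_equal(nrow(b), 1)
  expect_equal(b$midpoint, 150)
  expect_equal(b$mean_r2, 0.4)
  set.seed(8)
  pairs2 <- tibble::tibble(pos1 = 0, pos2 = 0,
                           distance = sample(1:1000, 400, TRUE),
                           r2 = runif(400))
  b2 <- bin_ld(pairs2, bin_width = 100)
  bin_idx <- floor(pairs2$distance / 100)
  byhand <- tapply(pairs2$r2, bin_idx, mean)
  byhand <- byhand[order(as.numeric(names(byhand)))]
  expect_equal(b2$mean_r2, as.numeric(byhand))
  # width-1 bins degenerate to per-distance means
  b3 <- bin_ld(pairs2, bin_width = 1)
  expect_equal(nrow(b3), length(unique(pairs2$distance)))
})

test_that("Sved fit recovers beta from noiseless curves to 0.1%", {
  d <- seq(50, 9950, by = 100)
  for (beta in c(1e-5, 1e-4, 1e-3)) {
    bins <- tibble::tibble(midpoint = d,
                           mean_r2 = 1 / (1 + 4 * beta * d) + 1 / 20,
                           n_pairs = 50L)
    f <- fit_sved(bins, n = 20)
    expect_lt(abs(f$beta - beta) / beta, 1e-3)
  }
  flat <- tibble::tibble(midpoint = d, mean_r2 = 1 / 20, n_pairs = 10L)
  expect_equal(fit_sved(flat, n = 20)$beta, 0)
})

test_that("Sved fit tolerates noise and round-trips the LD distance", {
  set.seed(90)
  beta <- 1e-4; d <- seq(50, 9950, by = 100)
  errs <- vapply(1:100, function(i) {
    bins <- tibble::tibble(
      midpoint = d,
      mean_r2 = 1 / (1 + 4 * beta * d) + 1 / 20 + rnorm(length(d), 0, 0.01),
      n_pairs = 50L)
    abs(fit_sved(bins, n = 20)$beta - beta) / beta
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
  bins <- tibble::tibble(midpoint = d,
                         mean_r2 = 1 / (1 + 4 * beta * d) + 1 / 20,
                         n_pairs = 50L)
  f <- fit_sved(bins, n = 20)
  dd <- ld_distance_at(f, 0.33)
  expect_equal(1 / (1 + 4 * f$beta * dd) + 1 / 20, 0.33, tolerance = 1e-9)
  # model intercept: target 1 + 1/n -> distance 0
  expect_equal(ld_distance_at(f, 1 + 1 / 20), 0)
})

test_that("useful-LD inversion matches the closed form without correction", {
  bins <- tibble::tibble(midpoint = seq(50, 9950, by = 100),
                         mean_r2 = 1 / (1 + 4e-4 * seq(50, 9950, by = 100)),
                         n_pairs = 10L)
  f <- fit_sved(bins, n = Inf)
  expect_equal(ld_distance_at(f, 0.33), (1 / 0.33 - 1) / (4 * 1e-4),
               tolerance = 1e-6)
  expect_error(ld_distance_at(f, -1), "exceed")
  flat <- fit_sved(tibble::tibble(midpoint = c(50, 150, 250),
                                  mean_r2 = 0.05, n_pairs = 1L), n = 20)
  expect_warning(dd <- ld_distance_at(flat, 0.33), "never decays")
  expect_equal(dd, Inf)
})

test_that("tidy, glance and autoplot work on fitted objects", {
  bins <- tibble::tibble(midpoint = seq(50, 950, by = 100),
                         mean_r2 = 1 / (1 + 4e-4 * seq(50, 950, by = 100)),
                         n_pairs = 10L)
  f <- fit_sved(bins, n = Inf)
  expect_equal(tidy(f)$term, "beta")
  expect_equal(glance(f)$n_bins, 10)
  expect_s3_class(autoplot(f), "ggplot")
  tr <- treatment_rate(read_ma_lines())
  expect_s3_class(autoplot(tr), "ggplot")
  expect_equal(glance(tr)$n_lines, 15)
})
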