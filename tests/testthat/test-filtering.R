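test_that("hard filter removes low QUAL, low QD and MQ0-heavy sites", {
  calls <- dplyr::bind_rows(
    make_site(100, c(ANC = "hom_ref", L01 = "het"), qual = 25, qd = 10),
    make_site(200, c(ANC = "hom_ref", L01 = "het"), qual = 40, qd = 10,
              mq0 = 5L, dp = 10L),
    make_site(300, c(ANC = "hom_ref", L01 = "het"), qual = 40, qd = 10),
    make_site(400, c(ANC = "hom_ref", L01 = "het"), qual = 100, qd = 4)
  )
  # site 200: dp_site = 10 * 2 = 20, MQ0 = 5 >= 4 and 5/20 > 0.1 -> removed
  out <- hard_filter_sites(calls)
  expect_setequal(unique(out$pos), 300)
})

test_that("hard filter sets aside sites with missing annotations", {
  calls <- dplyr::bind_rows(
    make_site(10, c(L01 = "het"), qual = NA),
    make_site(20, c(L01 = "het"))
  )
  expect_message(out <- hard_filter_sites(calls), "set aside")
  expect_equal(unique(out$pos), 20)
  expect_equal(unique(attr(out, "unevaluable")$pos), 10)
})

test_that("hard filter keeps only biallelic sites", {
  tri <- dplyr::bind_rows(
    make_site(50, c(L01 = "het"), alt = "T"),
    make_site(50, c(L02 = "het"), alt = "G")
  )
  expect_equal(nrow(hard_filter_sites(tri)), 0)
})

test_that("read-support filter zeroes out-of-contract records (strict bounds)", {
  calls <- dplyr::bind_rows(
    make_site(1, c(L01 = "het"), insert = 700L),
    make_site(2, c(L01 = "het"), insert = 300L),
    make_site(3, c(L01 = "het"), insert = 100L),  # boundary: strict
    make_site(4, c(L01 = "het"), insert = 600L),  # boundary: strict
    make_site(5, c(L01 = "het"), proper = 0.5)
  )
  out <- filter_read_support(calls)
  zeroed <- dplyr::filter(out, gt == "missing")
  expect_setequal(zeroed$pos, c(1, 3, 4, 5))
  expect_true(all(zeroed$dp == 0))
  expect_identical(dplyr::filter(out, pos == 2),
                   dplyr::filter(calls, pos == 2))
})

test_that("absent read-support summaries pass through with a message", {
  calls <- make_site(1, c(L01 = "het"))
  calls$median_insert <- NA_integer_
  calls$proper_pair_fraction <- NA_real_
  expect_message(out <- filter_read_support(calls), "pass through")
  expect_equal(out$gt, "het")
})

test_that("callable band is inclusive at 9 and 75", {
  m <- compute_callable(c(5, 9, 75, 76))
  expect_equal(sum(m$end - m$start), 2)
  m2 <- compute_callable(rep(28, 1000))
  expect_equal(sum(m2$end - m2$start), 1000)
  expect_error(compute_callable(c(-1, 5)), "negative")
})

test_that("callable totals match the per-position oracle on random depths", {
  set.seed(101)
  for (rep in 1:5) {
    d <- rnbinom(1e4, mu = 28, size = 3)
    m <- compute_callable(d)
    expect_equal(sum(m$end - m$start), oracle_callable(d))
  }
  # interval bookkeeping: sorted, non-overlapping, within bounds
  d <- rnbinom(1e4, mu = 28, size = 3)
  m <- compute_callable(d)
  expect_true(all(diff(m$start) > 0))
  expect_true(all(m$end > m$start))
  expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
})

test_that("cluster flags match the brute-force window oracle", {
  calls <- purrr::map_dfr(c(100, 110, 120, 500), function(p) {
    make_site(p, c(L01 = "het"))
  })
  out <- annotate_clusters(calls)
  expect_setequal(dplyr::filter(out, cluster_flag)$pos, c(100, 110, 120))

  calls2 <- purrr::map_dfr(c(100, 500), function(p) make_site(p, c(L01 = "het")))
  expect_false(any(annotate_clusters(calls2)$cluster_flag))

  set.seed(55)
  for (rep in 1:5) {
    pos <- sort(sample.int(5e3, 150))
    calls3 <- purrr::map_dfr(pos, function(p) make_site(p, c(L01 = "het")))
    out3 <- annotate_clusters(calls3)
    expect_equal(out3$cluster_flag[order(out3$pos)],
                 oracle_cluster_flags(pos))
  }
})

test_that("cross-sample filter counts carriers, ancestor included", {
  calls <- dplyr::bind_rows(
    make_site(10, c(ANC = "hom_ref", L01 = "het", L02 = "het", L03 = "het")),
    make_site(20, c(ANC = "hom_ref", L01 = "het", L02 = "hom_ref",
                    L03 = "hom_ref")),
    make_site(30, c(ANC = "het", L01 = "het", L02 = "het", L03 = "hom_ref"))
  )
  out <- cross_sample_filter(calls)
  expect_setequal(unique(out$pos), 20)
  # excluding the ancestor keeps the 2-offspring + ancestor site
  out2 <- cross_sample_filter(calls, include_ancestor = FALSE,
                              ancestor = "ANC")
  expect_setequal(unique(out2$pos), c(20, 30))
})

test_that("carrier counts match a brute-force scan on random tables", {
  set.seed(9)
  sm <- c("ANC", paste0("L", 1:6))
  calls <- purrr::map_dfr(1:60, function(p) {
    gts <- sample(c("hom_ref", "het", "hom_alt"), length(sm), TRUE,
                  prob = c(0.7, 0.2, 0.1))
    make_site(p * 10, setNames(gts, sm))
  })
  out <- cross_sample_filter(calls, max_samples = 2)
  by_hand <- calls |>
    dplyr::group_by(pos) |>
    dplyr::summarise(n = sum(gt != "hom_ref")) |>
    dplyr::filter(n <= 2)
  expect_setequal(unique(out$pos), by_hand$pos)
})

test_that("het support needs three reads on both alleles", {
  calls <- dplyr::bind_rows(
    make_site(10, c(L01 = "het"), ad = list(L01 = c(3, 3))),
    make_site(20, c(L01 = "het"), ad = list(L01 = c(2, 10))),
    make_site(30, c(L01 = "hom_alt"), ad = list(L01 = c(0, 12)))
  )
  out <- het_support_filter(calls)
  expect_setequal(unique(out$pos), c(10, 30))
  expect_equal(dplyr::filter(out, pos == 30)$gt, "hom_alt")
})

test_that("classification separates point, LOH and repeat-masked indels", {
  calls <- dplyr::bind_rows(
    make_site(10, c(ANC = "hom_ref", L01 = "het", L02 = "hom_ref"),
              ref = "G", alt = "A"),
    make_site(20, c(ANC = "het", L01 = "hom_ref", L02 = "het")),
    make_site(30, c(ANC = "hom_ref", L01 = "het", L02 = "hom_ref"),
              ref = "A", alt = "AT"),
    make_site(40, c(ANC = "hom_ref", L01 = "het", L02 = "hom_ref"),
              ref = "A", alt = "AT")
  )
  rmask <- tibble::tibble(chrom = "chr1", start = 25L, end = 35L)
  out <- classify_candidates(calls, "ANC", rmask)
  expect_equal(dplyr::filter(out, pos == 10)$class, "point")
  expect_equal(dplyr::filter(out, pos == 10)$spectrum, "C:G>T:A")
  expect_equal(dplyr::filter(out, pos == 20)$class, "LOH")
  expect_equal(dplyr::filter(out, pos == 20)$sample, "L01")
  expect_true(dplyr::filter(out, pos == 30)$likely_false)
  expect_false(dplyr::filter(out, pos == 40)$likely_false)
  expect_error(classify_candidates(calls, "NOPE"), "ancestor")
})

test_that("pipeline recovers exactly the simulated true mutations", {
  cfg <- sim_config(genome_length = 2e4, seed = 3,
                    true_mu = c("indoor" = 0, "outdoor-noUV" = 5e-7,
                                "outdoor-UV" = 1e-6))
  sim <- simulate_ma_experiment(cfg)
  p <- run_ma_pipeline(sim$calls, sim$depth,
                       repeat_mask = sim$truth$repeat_mask)
  pts <- dplyr::filter(p$candidates, class == "point")
  expect_setequal(paste(pts$sample, pts$pos),
                  paste(sim$truth$true_mutations$sample,
                        sim$truth$true_mutations$pos))
  # monotone survival through the cascade
  expect_true(all(diff(p$report$sites[-nrow(p$report)]) <= 0))
})

test_that("a table of 3-sample artifacts yields no candidates", {
  calls <- purrr::map_dfr(c(100, 900, 1700), function(p) {
    make_site(p, c(ANC = "hom_ref", L01 = "het", L02 = "het", L03 = "het"))
  })
  depth <- list(ANC = rep(28L, 2000), L01 = rep(28L, 2000),
                L02 = rep(28L, 2000), L03 = rep(28L, 2000))
  p <- run_ma_pipeline(calls, depth)
  expect_equal(nrow(p$candidates), 0)
})

test_that("pipeline output is invariant to sample row order", {
  cfg <- sim_config(genome_length = 1e4, seed = 8,
                    true_mu = c("indoor" = 1e-6, "outdoor-noUV" = 1e-6,
                                "outdoor-UV" = 1e-6))
  sim <- simulate_ma_experiment(cfg)
  p1 <- run_ma_pipeline(sim$calls, sim$depth)
  shuffled <- dplyr::arrange(sim$calls, sample, pos)
  p2 <- run_ma_pipeline(shuffled, sim$depth)
  expect_equal(p1$candidates, p2$candidates)
})

test_that("clean-data sensitivity is total with zero false positives", {
  cfg <- sim_config(genome_length = 5e4, seed = 31, seq_error_rate = 0,
                    depth_dispersion = 0, artifact_site_rate = 0,
                    indel_artifact_rate = 0, loh_rate = 0,
                    true_mu = c("indoor" = 2e-7, "outdoor-noUV" = 2e-7,
                                "outdoor-UV" = 2e-7))
  sim <- simulate_ma_experiment(cfg)
  p <- run_ma_pipeline(sim$calls, sim$depth)
  pts <- dplyr::filter(p$candidates, class == "point")
  truth_keys <- paste(sim$truth$true_mutations$sample,
                      sim$truth$true_mutations$pos)
  expect_gt(length(truth_keys), 0)
  expect_setequal(paste(pts$sample, pts$pos), truth_keys)
})
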