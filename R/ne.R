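#' Effective population size from diversity and mutation rate
#'
#' Under neutral equilibrium the population mutation parameter of a diploid
#' is `theta = 4 Ne mu`, and synonymous-site diversity estimates theta, so
#' `Ne = pi_s / (4 mu)`. Scaling both inputs by the same factor leaves Ne
#' unchanged.
#'
#' @param pi_s Per-site synonymous nucleotide diversity (> 0).
#' @param mu Mutation rate per site per generation (> 0).
#' @return One-row tibble of class `ne_estimate`: `pi_s, mu, theta, ne,
#'   ne_2sf` (rounded to two significant figures).
#' @export
#' @examples
#' effective_size(0.00093, 2.38e-10)  # ~9.8e5
effective_size <- function(pi_s, mu) {
  if (pi_s <= 0 || mu <= 0) abort("`pi_s` and `mu` must be > 0")
  ne <- pi_s / (4 * mu)
  out <- tibble(pi_s = pi_s, mu = mu, theta = pi_s,
                ne = ne, ne_2sf = signif(ne, 2))
  class(out) <- c("ne_estimate", class(out))
  out
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne = %.4g (2 s.f. %.2g) from pi_s = %g, mu = %g\n",
              x$ne, x$ne_2sf, x$pi_s, x$mu))
  invisible(as_tibble(x))
}

#' @rdname effective_size
#' @param x An `ne_estimate`.
#' @param ... Unused.
#' @method glance ne_estimate
#' @export
glance.ne_estimate <- function(x, ...) as_tibble(x)

#' Run the full MA-to-Ne analysis
#'
#' Orchestrates the pipeline end to end: simulate an MA experiment (or use
#' a supplied per-line table), filter candidates, estimate per-treatment
#' rates and the coding-genome expectation, measure spike-in recall,
#' summarise diversity and LD on a coalescent population sample, and
#' combine synonymous diversity with the chosen treatment's rate into Ne.
#' Each stage is optional: with `lines` supplied the simulation/filtering
#' stages are skipped; without `popgen`, the Ne section is marked absent.
#' The report is fully determined by the configuration and seed.
#'
#' @param sim_cfg Optional [sim_config()] for the MA stage.
#' @param lines Optional per-line tibble (`sample, treatment, k, L, g`)
#'   used directly for rate estimation (e.g. [read_ma_lines()]).
#' @param n_spikes Spike-in count for FN estimation (0 disables; only used
#'   with `sim_cfg`).
#' @param popgen Optional list `(n_haplotypes, theta)` for the coalescent
#'   population stage; `NULL` skips diversity/LD/Ne.
#' @param pi_s Optional externally supplied synonymous diversity for the
#'   Ne stage (overrides the coalescent estimate).
#' @param ne_treatment Treatment whose mean rate enters Ne
#'   (default `"outdoor-UV"`).
#' @param coding_size Coding-genome size for [coding_expectation()].
#' @param seed Master seed.
#' @return A list of class `ma_report` with elements `rates`,
#'   `coding_expectation`, `fn`, `diversity`, `ld`, `ne`, `provenance`.
#' @export
run_full_analysis <- function(sim_cfg = NULL, lines = NULL,
                              n_spikes = 0, popgen = NULL, pi_s = NULL,
                              ne_treatment = "outdoor-UV",
                              coding_size = 17.4e6, seed = 1L) {
  report <- list()
  fn <- NULL

  if (!is.null(sim_cfg)) {
    sim_cfg$seed <- as.integer(seed)
    sim <- simulate_ma_experiment(sim_cfg)
    pipe <- run_ma_pipeline(sim$calls, sim$depth,
                            ancestor = "ANC",
                            repeat_mask = sim$truth$repeat_mask)
    totals <- total_callable(pipe$masks)
    pts <- pipe$candidates %>% filter(.data$class == "point")
    lines_sim <- sim$samples %>%
      filter(!.data$is_ancestor) %>%
      left_join(count(pts, .data$sample, name = "k"), by = "sample") %>%
      left_join(totals, by = "sample") %>%
      mutate(k = tidyr::replace_na(.data$k, 0L), L = .data$total,
             g = sim_cfg$generations) %>%
      select("sample", "treatment", "k", "L", "g")
    if (is.null(lines)) lines <- lines_sim
    report$filter_report <- pipe$report
    report$candidates <- pipe$candidates
    report$spectrum <- mutation_spectrum(pipe$candidates)
    if (n_spikes > 0) {
      sp <- spike_in(sim$calls, pipe$masks, n = n_spikes,
                     seed = seed + 1L, depth = sim$depth,
                     samples = setdiff(sim$samples$sample, "ANC"))
      pipe2 <- run_ma_pipeline(sp$calls, pipe$masks, ancestor = "ANC",
                               repeat_mask = sim$truth$repeat_mask)
      fn <- spikein_fn(sp$truth,
                       pipe2$candidates %>% filter(.data$class == "point"))
    }
  }
  if (is.null(lines)) abort("supply `sim_cfg` or `lines`")

  rates <- treatment_rate(lines)
  report$rates <- rates
  report$coding_expectation <- coding_expectation(lines,
                                                  coding_size = coding_size)
  report$fn <- fn

  if (!is.null(popgen)) {
    cs <- simulate_coalescent(popgen$n_haplotypes, popgen$theta,
                              seed = seed + 2L)
    gm <- as_genotype_matrix(cs, ploidy = 1,
                             callable_length = popgen$callable_length %||% 1)
    report$diversity <- diversity_stats(gm)
    pairs <- ld_r2(genotype_matrix(gm$dosage, gm$positions,
                                   callable_length = gm$callable_length,
                                   ploidy = 1),
                   maf_min = 0.05, max_distance = 1e5)
    report$ld <- if (nrow(pairs) >= 3) {
      bins <- bin_ld(pairs, bin_width = 100)
      if (nrow(bins) >= 3) fit_sved(bins, n = popgen$n_haplotypes) else NULL
    } else NULL
  }

  mu_ne <- rates %>% filter(.data$treatment == ne_treatment) %>%
    pull(.data$mean_rate)
  pi_for_ne <- pi_s %||%
    (if (!is.null(report$diversity)) report$diversity$pi else NULL)
  report$ne <- if (length(mu_ne) == 1 && mu_ne > 0 &&
                   !is.null(pi_for_ne) && pi_for_ne > 0) {
    effective_size(pi_for_ne, mu_ne)
  } else {
    NULL  # absent: no usable mu or pi_s
  }

  report$provenance <- list(
    seed = as.integer(seed),
    ne_treatment = ne_treatment,
    coding_size = coding_size,
    thresholds = list(callable = c(9, 75), hard_filter = c(qual = 30, qd = 5,
                      mq0 = 4, mq0_frac = 0.1), cluster = c(50, 3),
                      max_shared = 2, min_support = 3),
    package_version = as.character(utils::packageVersion("mutaccum"))
  )
  structure(report, class = "ma_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ma_report <- function(x, ...) {
  cat("== MA analysis report ==\n")
  if (!is.null(x$filter_report)) {
    cat("\nFilter cascade:\n"); print(x$filter_report)
  }
  cat("\nTreatment rates:\n"); print(tidy(x$rates))
  cat("\nCoding-genome expectation (mutations/generation):\n")
  print(x$coding_expectation)
  if (!is.null(x$fn)) { cat("\n"); print(x$fn) }
  if (!is.null(x$diversity)) { cat("\nDiversity:\n"); print(x$diversity) }
  if (!is.null(x$ld)) { cat("\n"); print(x$ld) }
  if (!is.null(x$ne)) { cat("\n"); print(x$ne) } else {
    cat("\nNe: not computed (missing diversity or rate input)\n")
  }
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' @param report An `ma_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  to_json <- list(
    rates = as_tibble(report$rates),
    coding_expectation = report$coding_expectation,
    fn = if (!is.null(report$fn)) as_tibble(report$fn) else NULL,
    diversity = report$diversity,
    ld = if (!is.null(report$ld)) glance(report$ld) else NULL,
    ne = if (!is.null(report$ne)) as_tibble(report$ne) else NULL,
    provenance = report$provenance
  )
  jsonlite::write_json(to_json[!vapply(to_json, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
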