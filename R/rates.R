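#' Per-line mutation rate
#'
#' The per-line rate is `mu_i = k / (L * g)`: verified point mutations per
#' callable site per generation. The denominator is the number of callable
#' positions (not 2L): rates are per site, matching how callable sites are
#' counted.
#'
#' @param k Verified point-mutation count(s).
#' @param L Callable sites per line.
#' @param g Generations.
#' @return Numeric rate(s), mutations per site per generation.
#' @export
#' @examples
#' per_line_rate(1, 126.3e6, 20)
per_line_rate <- function(k, L, g) {
  if (any(L <= 0)) abort("`L` must be > 0.")
  if (any(g < 1)) abort("`g` must be >= 1.")
  if (any(k < 0)) abort("`k` must be >= 0.")
  k / (L * g)
}

#' Exact (Garwood) Poisson confidence bounds on a count
#'
#' Two-sided exact bounds from chi-square quantiles:
#' lower = chisq(alpha/2, 2k)/2 (0 when k = 0),
#' upper = chisq(1 - alpha/2, 2k + 2)/2. Both bounds are non-decreasing
#' in k and the interval is conservative (coverage >= 1 - alpha).
#'
#' @param k Non-negative count(s).
#' @param alpha Two-sided error rate (default 0.05 for 95% bounds).
#' @return Tibble with columns `k`, `lower`, `upper` (count scale).
#' @export
#' @examples
#' poisson_ci(0)   # upper bound 3.689
#' poisson_ci(55)  # 41.4 to 71.6
poisson_ci <- function(k, alpha = 0.05) {
  if (any(k < 0)) abort("`k` must be >= 0.")
  lower <- ifelse(k == 0, 0, qchisq(alpha / 2, 2 * k) / 2)
  upper <- qchisq(1 - alpha / 2, 2 * k + 2) / 2
  tibble(k = k, lower = lower, upper = upper)
}

#' Per-treatment mutation rates with exact Poisson intervals
#'
#' The treatment mean is the arithmetic mean of per-line rates. The
#' confidence interval applies exact Poisson (Garwood) bounds to the pooled
#' mutation count of the treatment and scales them by the summed
#' site-generations `sum(L_i * g_i)`. Treatments with zero observed
#' mutations report mean 0 and the upper bound only (`upper_only = TRUE`);
#' a conventional rendering that borrows the smallest positive treatment
#' mean as "< mean" is available from the `display` column.
#'
#' @param lines Tibble with columns `sample`, `treatment`, `k` (verified
#'   point mutations), `L` (callable sites) and `g` (generations; a single
#'   `g` column or the `generations` argument).
#' @param generations Used when `lines` lacks a `g` column.
#' @param alpha Two-sided error rate for the interval.
#' @return Tibble of class `treatment_rates`: one row per treatment with
#'   `n_lines, k_total, site_gens, mean_rate, ci_low, ci_high, upper_only,
#'   display`, plus a `lines` attribute carrying per-line rates.
#' @export
#' @examples
#' tbl <- read_ma_lines()
#' treatment_rate(tbl)
treatment_rate <- function(lines, generations = NULL, alpha = 0.05) {
  if (!"g" %in% names(lines)) {
    if (is.null(generations)) abort("supply `g` column or `generations`")
    lines$g <- generations
  }
  if (nrow(lines) == 0) abort("empty line table")
  lines <- lines %>% mutate(rate = per_line_rate(.data$k, .data$L, .data$g))
  out <- lines %>%
    group_by(.data$treatment) %>%
    summarise(
      n_lines = n(),
      k_total = sum(.data$k),
      site_gens = sum(.data$L * .data$g),
      mean_rate = mean(.data$rate),
      .groups = "drop"
    )
  ci <- poisson_ci(out$k_total, alpha)
  out <- out %>% mutate(
    ci_low = ci$lower / .data$site_gens,
    ci_high = ci$upper / .data$site_gens,
    upper_only = .data$k_total == 0
  )
  ref <- out %>% filter(!.data$upper_only) %>% pull(.data$mean_rate)
  ref <- if (length(ref) > 0) min(ref) else NA_real_
  out <- out %>% mutate(
    display = if_else(
      .data$upper_only & !is.na(ref),
      sprintf("<%.3g (NA)", ref),
      sprintf("%.3g (%.3g to %.3g)", .data$mean_rate, .data$ci_low,
              .data$ci_high))
  )
  attr(out, "lines") <- lines
  attr(out, "alpha") <- alpha
  class(out) <- c("treatment_rates", class(out))
  out
}

#' @export
print.treatment_rates <- function(x, ...) {
  cat("Per-treatment mutation rates (per site per generation)\n")
  NextMethod()
  invisible(x)
}

#' @rdname treatment_rate
#' @param x A `treatment_rates` object.
#' @param ... Unused.
#' @method tidy treatment_rates
#' @export
tidy.treatment_rates <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "lines") <- NULL
  attr(out, "alpha") <- NULL
  out %>%
    select("treatment", "n_lines", "k_total", "mean_rate",
           "ci_low", "ci_high", "upper_only")
}

#' @rdname treatment_rate
#' @method glance treatment_rates
#' @export
glance.treatment_rates <- function(x, ...) {
  lines <- attr(x, "lines")
  tibble(n_treatments = nrow(x), n_lines = nrow(lines),
         k_total = sum(x$k_total), site_gens = sum(x$site_gens),
         alpha = attr(x, "alpha"))
}

#' Expected mutations per generation in the coding genome
#'
#' Scales each line's per-site rate by the size of the protein-coding
#' fraction of the genome to give expected coding mutations per generation,
#' then summarises per treatment with the sample standard deviation
#' (n - 1 denominator) across lines.
#'
#' @param lines Per-line tibble (`treatment, k, L, g`), or a
#'   `treatment_rates` object (its `lines` attribute is used).
#' @param coding_size Protein-coding genome size in bp (default 17.4 Mb).
#' @param generations Used when `lines` lacks a `g` column.
#' @return Tibble: `treatment, n_lines, mean_expected, sd_expected`
#'   (mutations per generation in coding DNA).
#' @export
coding_expectation <- function(lines, coding_size = 17.4e6,
                               generations = NULL) {
  if (inherits(lines, "treatment_rates")) lines <- attr(lines, "lines")
  if (!"g" %in% names(lines)) {
    if (is.null(generations)) abort("supply `g` column or `generations`")
    lines$g <- generations
  }
  lines %>%
    mutate(rate = per_line_rate(.data$k, .data$L, .data$g),
           expected = .data$rate * coding_size) %>%
    group_by(.data$treatment) %>%
    summarise(n_lines = n(),
              mean_expected = mean(.data$expected),
              sd_expected = if (n() > 1) sd(.data$expected) else 0,
              .groups = "drop")
}

#' Mutation spectrum of point candidates
#'
#' Normalizes each single-nucleotide change to its pyrimidine-first
#' complementary-pair class (a G>A change on the reference strand is the
#' same event as C>T on the other strand, labelled `C:G>T:A`) and tallies
#' classes, marking each as transition or transversion.
#'
#' @param candidates Candidate tibble with `ref`, `alt` (and optionally
#'   `class`, in which case only `class == "point"` rows are used).
#' @return Tibble `spectrum, type, n`; zero rows for an empty input.
#' @export
mutation_spectrum <- function(candidates) {
  if ("class" %in% names(candidates)) {
    candidates <- candidates %>% filter(.data$class == "point")
  }
  if (nrow(candidates) == 0) {
    return(tibble(spectrum = character(), type = character(), n = integer()))
  }
  if (any(nchar(candidates$ref) != 1 | nchar(candidates$alt) != 1)) {
    abort("mutation_spectrum is defined for single-nucleotide changes only")
  }
  transitions <- c("C:G>T:A", "T:A>C:G")
  candidates %>%
    mutate(spectrum = spectrum_label(.data$ref, .data$alt)) %>%
    count(.data$spectrum, name = "n") %>%
    mutate(type = if_else(.data$spectrum %in% transitions,
                          "transition", "transversion")) %>%
    select("spectrum", "type", "n")
}

#' Read a bundled or user per-line MA summary table
#'
#' The bundled table (`ma_lines.tsv`) is the per-line summary of a
#' 15-line duckweed MA experiment: five lines in each of three treatments
#' (indoor, outdoor without UV, outdoor with UV), propagated for 20
#' generations, with the verified point-mutation count and callable
#' genome size (Mb) per line.
#'
#' @param path TSV path; default is the bundled table.
#' @param generations Generations column to attach.
#' @return Tibble `sample, treatment, k, L, g` with `L` in sites (bp).
#' @export
read_ma_lines <- function(path = system.file("extdata", "ma_lines.tsv",
                                             package = "mutaccum"),
                          generations = 20) {
  readr::read_tsv(path, show_col_types = FALSE) %>%
    mutate(L = .data$callable_mb * 1e6, k = .data$mutations,
           g = generations) %>%
    select("sample", "treatment", "k", "L", "g")
}
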