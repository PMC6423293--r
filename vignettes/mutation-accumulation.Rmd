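---
title: "Estimating spontaneous mutation rates and effective population size from mutation-accumulation lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spontaneous mutation rates and effective population size from mutation-accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutaccum)
library(dplyr)
```

## The problem

Standing genetic diversity in a population reflects the balance between
mutational input and drift: for a diploid at neutral equilibrium,
$\theta = 4 N_e \mu$, where $\mu$ is the spontaneous mutation rate per site
per generation and $N_e$ the effective population size. Synonymous-site
nucleotide diversity $\pi_S$ estimates $\theta$, so a species with
unusually low diversity may have either a low mutation rate or a small
$N_e$ — and only an independent, direct measurement of $\mu$ can tell the
two apart.

Mutation-accumulation (MA) experiments provide that measurement. A single
ancestor founds replicate lines that are propagated through
single-descendant bottlenecks, so selection is nearly powerless and new
mutations accumulate at close to the spontaneous rate. In a clonal plant
such as the giant duckweed, replicate fronds can additionally be raised
under different environments (indoor, outdoor shielded from UV, outdoor
with UV) to ask whether natural conditions change the rate. After $g$
generations, each line is short-read sequenced alongside the ancestor, and
de novo mutations are the genotype differences that survive a stringent
filtering cascade.

This package implements the full desk-scale analysis: a synthetic-data
generator that emulates the MA design with known truth, the filtering
cascade, rate estimation with exact Poisson intervals, false-negative
estimation, population-genetic summaries (diversity, Tajima's D, Hudson's
$F_{ST}$, LD decay), and the final $N_e = \pi_S / 4\mu$ step.

## The filtering cascade

A candidate de novo mutation must survive, in order:

1. **Read support** (`filter_read_support()`): only properly paired reads
   with insert size strictly between 100 and 600 bp support a record;
   failing records are zeroed. Both bounds are exclusive, as the contract
   is "greater than 100 and less than 600".
2. **Callable band** (`compute_callable()`): positions covered by 9–75
   reads per sample, inclusive at both ends ("fewer than nine or greater
   than 75" excluded). The summed callable length $L_i$ per line is also
   the rate denominator, so variant counting and genome-size counting use
   the same mask.
3. **Hard site filters** (`hard_filter_sites()`): a site is removed when
   (MQ0 ≥ 4 AND MQ0/DP > 0.1) OR QUAL < 30 OR QD < 5, and multiallelic
   sites are dropped. The clauses are individually toggleable; sites with
   missing annotations are set aside rather than silently kept.
4. **Cluster removal** (`annotate_clusters()`): any variant inside a 50-bp
   window containing ≥ 3 variant sites is flagged and removed. Dense
   variant clusters in short-read data are overwhelmingly alignment
   artifacts; in validation work all Sanger-checked clustered variants
   proved false. The threshold is configurable: `min_count = 4` gives the
   literal "more than three in 50 bp" reading, `min_count = 3` the
   conventional 3-in-50 semantics used as default.
5. **Cross-sample sharing** (`cross_sample_filter()`): a genuine de novo
   mutation arises once; the probability of independent hits at the same
   site in $n$ lines scales as $\mu^n$. Variants carried by more than two
   samples are removed. Whether the ancestor counts as a carrier is not
   decidable from the design alone; we include it by default (a de novo
   candidate must be absent from the ancestor regardless) and expose
   `include_ancestor = FALSE`.
6. **Heterozygote support** (`het_support_filter()`): a heterozygous call
   needs ≥ 3 reads for *each* allele.
7. **Classification** (`classify_candidates()`): point mutation = ancestor
   hom-ref with exactly one heterozygous offspring; LOH = ancestor het
   with a homozygous offspring (gene conversion, excluded from the rate);
   indels are flagged and, when inside the repeat mask, marked
   likely-false. Spectra are reported pyrimidine-first (`C:G>T:A` etc.).

`run_ma_pipeline()` applies the stages in this order and reports the
number of sites surviving each one.

## Rate estimation

Each line contributes $\mu_i = k_i / (L_i\,g)$ — mutations per callable
site per generation; the denominator is callable positions, not $2L$,
which is the convention that makes the published per-line arithmetic
self-consistent. The treatment rate is the **arithmetic mean of per-line
rates**, not the pooled $\sum k / \sum L_i g$: with near-equal $L_i$ the
two differ only in the fourth digit, but only the mean-of-lines reading
reproduces the reference per-treatment values exactly.

Confidence intervals treat the pooled count $k$ as Poisson and use exact
Garwood bounds,
$\tfrac12\chi^2_{\alpha/2}(2k) \le \lambda \le
\tfrac12\chi^2_{1-\alpha/2}(2k+2)$, scaled by total site-generations. The
k = 0 upper bound is $3.689/\sum L_i g$. We note that the reference
treatment-rate intervals cannot be reproduced by Garwood, likelihood-ratio
or bootstrap constructions (the same Garwood bounds *do* reproduce the
published spike-in FN interval exactly), so the interval method is
documented here rather than guessed further; zero-count treatments are
reported both as a bare upper bound and in the conventional
"< smallest-positive-mean (NA)" rendering.

`coding_expectation()` scales per-line rates by the 17.4 Mb protein-coding
genome to expected coding mutations per generation, summarised with the
sample SD (n − 1) — the only denominator that reproduces the reference
value pair 0.0041 ± 0.0038.

## False-negative estimation

Two complementary routes:

* **Ancestral-heterozygote recall** (`het_recall_fn()`): every ancestor
  het should reappear in every clonal offspring, assessed with exactly
  the candidate thresholds (9–75× depth, ≥ 3 reads per allele). The mean
  per-offspring miss fraction with a t-interval across offspring is an
  *upper* bound on the FN rate, since true LOH also produces misses.
* **Spike-in recall** (`spike_in()` + `spikein_fn()`): synthetic
  heterozygous variants with allele fraction Normal(0.5, 0.1) are
  injected uniformly into callable regions and pushed through the
  identical pipeline; FN = missed/spiked with Garwood bounds. Injection
  happens at the variant-table level (allele-depth records), which is
  equivalent to read-level injection for every filter this pipeline
  applies. Spiked allele depth is `round(dp × af)`, so with depth ≥ 9 and
  af = 0.5 recall is guaranteed by construction — the basis of the
  round-trip tests. At realistic spike densities (1 per ≥ 100 kb)
  spike–spike clustering is negligible; when spiking densely for testing,
  `min_spacing` avoids manufacturing clusters that the cluster filter
  would then (correctly) remove.

`fn_correct_rate()` optionally inflates rates by $1/(1-\mathrm{FN})$;
headline rates are reported uncorrected.

## The synthetic-data generator

`simulate_ma_experiment()` emulates the study design: one diploid
ancestor, five lines in each of three treatments, $g = 20$
single-descendant generations, mean depth 28×. Defaults follow the
conditions the analysis targets; where the data-generating process is not
observable at desk scale we chose once:

* **Depth**: negative binomial, mean 28, size 10 (SD ≈ 10). Only the mean
  is externally fixed; overdispersion is required so that both edges of
  the 9–75 callable band are actually exercised. `depth_dispersion = 0`
  gives constant depth for exact-recovery tests.
* **True mutations**: per line Poisson($\mu L_\mathrm{callable} g$),
  placed uniformly over that line's callable positions, heterozygous with
  Binomial(depth, 0.5) allele depths; single-nucleotide only, since only
  point mutations enter the rate.
* **Nuisance signal**: ancestral het loci at 2.4 × 10⁻⁴ per bp (the
  empirical density of ~30,000 hets over a ~126 Mb callable genome), each
  subject to per-line LOH at rate 10⁻³; artifact sites at 5 × 10⁻⁶ per bp,
  half carried by ≥ 3 samples and half in ≤ 50-bp clusters of three
  (densities chosen so that desk-scale genomes of 10⁴–10⁶ bp contain
  enough artifacts to exercise every filter); indel artifacts placed
  preferentially in a simulated repeat mask; per-base sequencing error
  10⁻³, emitted as a record when ≥ 2 error reads pile up.
* **Streams**: per-line RNG seeds are derived deterministically from the
  master seed, so adding a line never perturbs the others, and identical
  configurations are byte-identical.

What the generator does *not* emulate: read-level alignment error,
mapping-quality structure along repeats, index hopping, or depth
autocorrelation along the genome. Passing tests therefore demonstrate the
*logic* of the cascade (sensitivity, specificity against the modelled
artifact classes, correct bookkeeping), not robustness to every failure
mode of real alignments.

`simulate_coalescent()` is a standard infinite-sites Hudson simulator
(exponential coalescence times, Poisson mutations on branches) used to
calibrate the diversity estimators against closed forms
($E[S] = \theta\sum 1/i$, $E[\pi] = \theta$).

## Population-genetic summaries

Diversity uses per-site unbiased heterozygosity $2\hat p(1-\hat p)
\frac{n}{n-1}$ summed over sites and divided by the callable length;
missing genotypes reduce $n$ site-wise. `coding_diversity()` obtains
$\pi_S$/$\pi_N$ with Nei–Gojobori mutational-opportunity site counts from
codon degeneracy (every sense codon's synonymous + nonsynonymous sites sum
to exactly 3). Tajima's D uses the standard constants; it is undefined at
S = 0 and signalled as such rather than returned as 0. $F_{ST}$ is
Hudson's ratio of averages $1 - \overline{\pi_W}/\overline{\pi_B}$ —
chosen because it is well defined as a genome-wide ratio and robust to
rare variants; the reference analysis used a package default without
naming its estimator.

LD is computed on unphased dosages (Rogers–Huff $r$ = Pearson correlation
of dosage vectors), appropriate for clonal samples without phasing.
Pairs are restricted to 100 kb by default and binned in non-overlapping
100-bp windows; `fit_sved()` fits
$E(r^2) = \frac{1}{1 + 4\beta d} + \frac{1}{n}$ by pair-count-weighted
least squares with $\beta \ge 0$ enforced (the printed form of this
equation in the source literature contains a typographical garble
"(1−/(1+4βd))"; we use the standard Sved decay with the additive
small-sample correction, which is what the $1/n$ term denotes). The
useful-LD distance inverts the fitted model at $r^2 = 0.33$:
$d = (1/(r^2 - 1/n) - 1)/(4\beta)$. Initialisation uses the half-decay
heuristic $\beta_0 = 1/(4 d_{1/2})$, with a bounded 1-D search as
fallback; a flat series returns the $\beta = 0$ boundary and an infinite
useful-LD distance, signalled.

## Worked desk-scale example

```{r rates}
lines <- read_ma_lines()
tr <- treatment_rate(lines)
tidy(tr)
coding_expectation(lines)
effective_size(0.00093, filter(tr, treatment == "outdoor-UV")$mean_rate)
```

The outdoor-UV mean of 2.38 × 10⁻¹⁰ per site per generation with
$\pi_S$ = 0.00093 gives $N_e \approx 9.8 \times 10^5$.

```{r sim}
cfg <- sim_config(genome_length = 2e4, seed = 3,
                  true_mu = c("indoor" = 0, "outdoor-noUV" = 5e-7,
                              "outdoor-UV" = 1e-6))
sim <- simulate_ma_experiment(cfg)
p <- run_ma_pipeline(sim$calls, sim$depth, repeat_mask = sim$truth$repeat_mask)
p$report
```

## Numerical and scale choices

Desk-scale problem sizes are deliberate: genomes of 10⁴–10⁶ bp, 200
replicate simulations for rate recovery, 5,000 coalescent replicates for
moment checks, 10,000 draws for CI coverage. These give Monte-Carlo
standard errors comfortably below the tolerances being checked while
keeping any single check in seconds to a couple of minutes. Coordinates
are 0-based half-open internally for intervals (BED convention) and
1-based for sites (VCF convention). Ties and degenerate inputs are
handled explicitly: S = 0 for Tajima's D, monomorphic populations for
$F_{ST}$, flat LD series, zero-count treatments, and empty candidate
tables all return signalled, documented values rather than silent zeros.

## Known limitations

* The treatment-rate CI construction is documented (Garwood on pooled
  counts) but intentionally does not match the unexplained reference
  intervals; see above.
* The LOH class survives to classification only when the sharing filter
  does not remove the underlying ancestral het site; with
  `include_ancestor = TRUE` and many carrier offspring this is rare, so
  LOH triage is primarily exercised through `classify_candidates()`
  directly.
* The coalescent has no recombination, selection or demography; it is a
  calibration harness for the estimators, not a model of the sampled
  populations.
* Genome-scale reference quantities (cohort $\pi_S$, SNP counts,
  $F_{ST}$ ranges, LD half-distances, the 1.6% het-recall FN) require the
  original sequencing data and are represented here by unit/format
  contracts plus the property tests above.
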