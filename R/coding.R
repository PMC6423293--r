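#' Synonymous / nonsynonymous site counting and SNP classification
#'
#' Nei-Gojobori-style site counting under the standard genetic code: each
#' position of each sense codon contributes the fraction of its three
#' possible single-base changes that leave the encoded amino acid unchanged
#' to the synonymous site total, and the complement to the nonsynonymous
#' total (changes creating a stop codon count as nonsynonymous), so the two
#' contributions sum to exactly 3 per codon. Variants supplied as 1-based
#' positions within the CDS are labelled `synonymous` or `nonsynonymous`
#' by translating the mutated codon.
#'
#' @param cds Coding sequence as a character scalar (length divisible by
#'   3, no internal stop codons, uppercase ACGT).
#' @param variants Optional tibble `pos, ref, alt` with `pos` 1-based in
#'   CDS coordinates.
#' @return A list of class `coding_sites`: `syn_sites`, `nonsyn_sites`
#'   (numeric totals), `per_codon` (tibble `codon_index, position,
#'   syn_fraction`) and, when variants are given, `snps` (input tibble
#'   with a `class` column).
#' @export
#' @examples
#' classify_coding_sites("ATGGGATAA")  # ATG GGA (TAA stop trimmed)
classify_coding_sites <- function(cds, variants = NULL) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) abort("CDS length must be divisible by 3")
  if (!grepl("^[ACGT]+$", cds)) abort("CDS must contain only ACGT")
  code <- Biostrings::GENETIC_CODE
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aas <- unname(code[codons])
  # trailing stop is allowed and dropped; internal stops are malformed
  if (length(codons) > 1 && aas[length(aas)] == "*") {
    codons <- codons[-length(codons)]
    aas <- aas[-length(aas)]
  }
  if (any(aas == "*")) abort("internal stop codon in CDS")

  syn_frac <- function(codon, pos) {
    aa <- code[[codon]]
    alts <- setdiff(BASES, substr(codon, pos, pos))
    mut <- vapply(alts, function(b) {
      x <- codon
      substr(x, pos, pos) <- b
      code[[x]]
    }, character(1))
    sum(mut == aa) / 3  # stops (mut == "*") are nonsynonymous
  }
  per_codon <- tidyr::expand_grid(codon_index = seq_along(codons),
                                  position = 1:3) %>%
    mutate(syn_fraction = purrr::map2_dbl(
      .data$codon_index, .data$position,
      function(i, p) syn_frac(codons[i], p)))

  out <- list(syn_sites = sum(per_codon$syn_fraction),
              nonsyn_sites = 3 * length(codons) - sum(per_codon$syn_fraction),
              per_codon = per_codon)
  if (!is.null(variants) && nrow(variants) > 0) {
    cls <- vapply(seq_len(nrow(variants)), function(i) {
      p <- variants$pos[i]
      ci <- (p - 1) %/% 3 + 1
      cp <- (p - 1) %% 3 + 1
      if (ci > length(codons)) return(NA_character_)
      codon <- codons[ci]
      if (substr(codon, cp, cp) != variants$ref[i]) {
        abort(sprintf("variant %d: ref %s does not match CDS", i, variants$ref[i]))
      }
      mut <- codon
      substr(mut, cp, cp) <- variants$alt[i]
      if (code[[mut]] == code[[codon]]) "synonymous" else "nonsynonymous"
    }, character(1))
    out$snps <- variants %>% mutate(class = cls)
  }
  structure(out, class = "coding_sites")
}

#' Diversity at synonymous and nonsynonymous sites
#'
#' Splits per-site heterozygosity across coding variants by their
#' synonymous/nonsynonymous class and scales by the corresponding
#' mutational-opportunity site totals to give pi_S and pi_N.
#'
#' @param g A `genotype_matrix` whose sites are coding variants with
#'   positions in CDS coordinates.
#' @param cds The coding sequence (character scalar).
#' @param ref,alt Reference and alternate alleles per site of `g` (in
#'   site order).
#' @return One-row tibble: `pi_s, pi_n, pi_n_pi_s, syn_sites,
#'   nonsyn_sites, n_syn_snps, n_nonsyn_snps`.
#' @export
coding_diversity <- function(g, cds, ref, alt) {
  stopifnot(inherits(g, "genotype_matrix"))
  cs <- classify_coding_sites(
    cds, tibble(pos = g$positions, ref = ref, alt = alt))
  h <- site_heterozygosity(g$dosage, g$ploidy)
  syn <- cs$snps$class == "synonymous"
  pi_s <- sum(h[syn], na.rm = TRUE) / cs$syn_sites
  pi_n <- sum(h[!syn], na.rm = TRUE) / cs$nonsyn_sites
  tibble(pi_s = pi_s, pi_n = pi_n,
         pi_n_pi_s = ifelse(pi_s > 0, pi_n / pi_s, NA_real_),
         syn_sites = cs$syn_sites, nonsyn_sites = cs$nonsyn_sites,
         n_syn_snps = sum(syn), n_nonsyn_snps = sum(!syn))
}
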