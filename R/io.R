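#' Write a site-call table as a multi-sample VCF
#'
#' Emits VCF 4.2 with per-sample `GT:AD:DP` and INFO fields `DP`, `QD`,
#' `MQ0`. Internal coordinates are already 1-based, matching VCF.
#'
#' @param calls Site-call tibble.
#' @param path Output path (plain text).
#' @param contig_length Declared contig length for the header.
#' @return `path`, invisibly.
#' @export
write_ma_vcf <- function(calls, path, contig_length = NULL) {
  samples <- sort(unique(calls$sample))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mutaccum",
    if (!is.null(contig_length)) {
      sprintf("##contig=<ID=%s,length=%d>", unique(calls$chrom)[1],
              as.integer(contig_length))
    },
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=MQ0,Number=1,Type=Integer,Description="Mapping quality zero count">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  wide <- calls %>%
    mutate(field = sprintf("%s:%d,%d:%d", gt_code[.data$gt],
                           .data$ad_ref, .data$ad_alt, .data$dp)) %>%
    select("chrom", "pos", "ref", "alt", "qual", "qd", "mq0", "dp_site",
           "sample", "field") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "field",
                       values_fill = "./.:0,0:0")
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%.8g\t.\tDP=%d;QD=%.8g;MQ0=%d\tGT:AD:DP\t%s",
    wide$chrom, wide$pos, wide$ref, wide$alt, wide$qual,
    wide$dp_site, wide$qd, wide$mq0,
    do.call(paste, c(lapply(samples, function(s) wide[[s]]), sep = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a site-call table
#'
#' Parses GT/AD/DP per sample and the INFO fields QD, MQ0 and DP via vcfR.
#' Read-support summaries (`proper_pair_fraction`, `median_insert`) are not
#' carried by VCF and come back as `NA` (treated as passing by
#' [filter_read_support()]).
#'
#' @param path VCF path.
#' @return Site-call tibble.
#' @export
read_ma_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_num <- function(key) {
    m <- stringr::str_match(fix$INFO, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    as.numeric(m)
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  dp_raw <- vcfR::extract.gt(v, element = "DP")
  samples <- colnames(gt_raw)
  decode <- c("0/0" = "hom_ref", "0|0" = "hom_ref",
              "0/1" = "het", "1/0" = "het", "0|1" = "het", "1|0" = "het",
              "1/1" = "hom_alt", "1|1" = "hom_alt")
  site <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                 ref = fix$REF, alt = fix$ALT,
                 qual = as.numeric(fix$QUAL), qd = info_num("QD"),
                 mq0 = as.integer(info_num("MQ0")),
                 dp_site = as.integer(info_num("DP")))
  purrr::map_dfr(samples, function(s) {
    ad <- stringr::str_split_fixed(ad_raw[, s], ",", 2)
    gt <- decode[gt_raw[, s]]
    gt[is.na(gt)] <- "missing"
    site %>% mutate(
      sample = s, gt = unname(gt),
      ad_ref = suppressWarnings(as.integer(ad[, 1])),
      ad_alt = suppressWarnings(as.integer(ad[, 2])),
      dp = suppressWarnings(as.integer(dp_raw[, s])),
      proper_pair_fraction = NA_real_, median_insert = NA_integer_)
  }) %>%
    mutate(ad_ref = tidyr::replace_na(.data$ad_ref, 0L),
           ad_alt = tidyr::replace_na(.data$ad_alt, 0L),
           dp = tidyr::replace_na(.data$dp, 0L)) %>%
    arrange(.data$chrom, .data$pos, .data$sample)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param mask Tibble with `chrom, start, end` and optionally `sample`
#'   (written as the name column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(mask, path) {
  cols <- c("chrom", "start", "end",
            if ("sample" %in% names(mask)) "sample")
  readr::write_tsv(mask[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED path; a fourth column, when present, is read as
#'   `sample`.
#' @return Tibble `chrom, start, end` (+ `sample`).
#' @export
read_bed <- function(path) {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE)
  nms <- c("chrom", "start", "end", "sample")[seq_len(min(4, ncol(first)))]
  readr::read_tsv(path, col_names = nms, show_col_types = FALSE,
                  col_select = seq_along(nms))
}

#' Write / read a simulation truth table
#'
#' @param truth A `sim_truth` (its `true_mutations` or `spiked` slot) or a
#'   plain tibble.
#' @param path TSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_truth_tsv <- function(truth, path) {
  tbl <- if (inherits(truth, "sim_truth")) {
    if (nrow(truth$true_mutations %||% tibble()) > 0) {
      truth$true_mutations
    } else {
      truth$spiked
    }
  } else truth
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
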