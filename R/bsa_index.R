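#' Per-pool SNP/InDel index
#'
#' The index of a site in one pool is the alternate-allele read count divided
#' by the total read count (REF reads + ALT reads) — an estimate of the
#' pooled allele frequency.
#'
#' @param ref_reads,alt_reads Non-negative integer vectors of read counts.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' compute_index(10, 30)  # 0.75
#' @export
compute_index <- function(ref_reads, alt_reads) {
  tot <- ref_reads + alt_reads
  if (any(tot <= 0)) {
    abort("zero total depth: the index is undefined; filter such sites first")
  }
  alt_reads / tot
}

#' Delta index between the two pools
#'
#' @param index_high,index_low Per-pool indices in `[0, 1]`.
#' @return `index_high - index_low`, in `[-1, 1]`. A large absolute value
#'   indicates allele-frequency divergence between the bulks, i.e. linkage to
#'   the trait locus.
#' @export
compute_delta <- function(index_high, index_low) {
  index_high - index_low
}

#' Filter configuration for the index scan
#'
#' Defaults follow standard QTL-seq practice: drop multi-allelic sites, sites
#' under 4x depth in either pool, sites with index below 0.3 in *both* pools
#' (shared sequencing error / rare alleles), and sites whose inferred
#' genotype class is identical in both pools (both indices in the same
#' homozygous band). The parental-recessive filter only applies to pools
#' derived from a biparental cross and is off for a natural population.
#'
#' @param min_index Low-index cutoff (default 0.3).
#' @param low_index_mode `"both"` (default) removes a site only when both
#'   pools are below `min_index`; `"either"` removes when either is.
#' @param min_depth Minimum total depth per pool (default 4).
#' @param drop_multiallelic Drop flagged multi-allelic sites (default TRUE).
#' @param drop_equal_genotypes Drop sites with both indices in the same
#'   homozygous band (default TRUE).
#' @param hom_band Half-width of the homozygous bands: both indices `<
#'   hom_band` or both `> 1 - hom_band` counts as "same genotype"
#'   (default 0.1).
#' @param parental_recessive_filter Optional cross-design filter
#'   (default FALSE).
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_index = 0.3, low_index_mode = c("both", "either"),
                          min_depth = 4, drop_multiallelic = TRUE,
                          drop_equal_genotypes = TRUE, hom_band = 0.1,
                          parental_recessive_filter = FALSE) {
  assert_scalar_num(min_index, "min_index", 0, 1 - 1e-9)
  assert_scalar_num(min_depth, "min_depth", 1)
  assert_scalar_num(hom_band, "hom_band", 0, 0.5)
  structure(list(min_index = min_index,
                 low_index_mode = match.arg(low_index_mode),
                 min_depth = min_depth,
                 drop_multiallelic = isTRUE(drop_multiallelic),
                 drop_equal_genotypes = isTRUE(drop_equal_genotypes),
                 hom_band = hom_band,
                 parental_recessive_filter = isTRUE(parental_recessive_filter)),
            class = "filter_config")
}

#' Index a pooled-variant table and apply the scan filters
#'
#' `bsa_index()` adds per-pool indices, total depths and the delta index to a
#' pooled-variant table. `bsa_filter()` applies the filter rules in a fixed,
#' reported order (first matching rule claims the site): multi-allelic;
#' depth below `min_depth` in either pool; low index (`min_index` rule);
#' equal genotype classes in both pools. The removal counts are attached as
#' a filter report, retrievable with [filter_report()].
#'
#' @param variants Pooled-variant tibble from [read_pooled_vcf()] or
#'   [sim_pooled_reads()].
#' @param config A [filter_config()].
#' @return `bsa_index()`: the tibble with columns `depth_high`, `depth_low`,
#'   `index_high`, `index_low`, `delta` added (indices are `NA` at zero
#'   depth). `bsa_filter()`: the retained, indexed tibble with a
#'   `filter_report` attribute.
#' @examples
#' v <- tibble::tibble(chrom = "Chr01", pos = 1:2, ref = "A", alt = "T",
#'                     vclass = "SNP", multiallelic = FALSE,
#'                     ad_high_ref = c(1L, 0L), ad_high_alt = c(19L, 20L),
#'                     ad_low_ref = c(18L, 19L), ad_low_alt = c(2L, 1L))
#' bsa_filter(v)
#' @export
bsa_index <- function(variants) {
  assert_cols(variants, c("ad_high_ref", "ad_high_alt", "ad_low_ref", "ad_low_alt"),
              "variants")
  variants |>
    mutate(
      depth_high = .data$ad_high_ref + .data$ad_high_alt,
      depth_low = .data$ad_low_ref + .data$ad_low_alt,
      index_high = ifelse(.data$depth_high > 0,
                          .data$ad_high_alt / .data$depth_high, NA_real_),
      index_low = ifelse(.data$depth_low > 0,
                         .data$ad_low_alt / .data$depth_low, NA_real_),
      delta = .data$index_high - .data$index_low
    )
}

#' @rdname bsa_index
#' @export
bsa_filter <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  x <- bsa_index(variants)
  n_in <- nrow(x)
  if (!"multiallelic" %in% names(x)) x$multiallelic <- FALSE

  # first matching rule claims the site
  rule <- rep(NA_character_, n_in)
  if (config$drop_multiallelic) {
    rule[is.na(rule) & x$multiallelic] <- "multiallelic"
  }
  low_depth <- x$depth_high < config$min_depth | x$depth_low < config$min_depth
  rule[is.na(rule) & low_depth] <- "depth"
  low_index <- if (config$low_index_mode == "both") {
    x$index_high < config$min_index & x$index_low < config$min_index
  } else {
    x$index_high < config$min_index | x$index_low < config$min_index
  }
  rule[is.na(rule) & !is.na(low_index) & low_index] <- "low_index"
  if (config$drop_equal_genotypes) {
    b <- config$hom_band
    same <- (x$index_high < b & x$index_low < b) |
      (x$index_high > 1 - b & x$index_low > 1 - b)
    rule[is.na(rule) & !is.na(same) & same] <- "equal_genotype"
  }

  keep <- is.na(rule)
  rule_names <- c("multiallelic", "depth", "low_index", "equal_genotype")
  n_removed <- vapply(rule_names, function(r) sum(rule == r, na.rm = TRUE),
                      integer(1))
  report <- tibble(rule = c(rule_names, "retained"),
                   removed = c(unname(n_removed), sum(keep)))
  out <- x[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filter report of a filtered variant table
#'
#' @param x The tibble returned by [bsa_filter()].
#' @return A tibble with columns `rule` and `removed`; the last row
#'   (`"retained"`) counts the surviving sites, so the column sums to the
#'   input size.
#' @export
filter_report <- function(x) {
  rep <- attr(x, "filter_report")
  if (is.null(rep)) abort("`x` carries no filter report; was it made by bsa_filter()?")
  rep
}
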