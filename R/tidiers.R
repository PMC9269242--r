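#' Tidy a window scan into one long window table
#'
#' @param x A [bsa_scan()] object.
#' @param ... Unused.
#' @return Tibble of all windows with a `track` column (`SNP`/`InDel`).
#' @export
tidy.bsa_scan <- function(x, ...) {
  bind_rows(mutate(x$snp, track = "SNP"),
            mutate(x$indel, track = "InDel")) |>
    dplyr::relocate("track")
}

#' One-row summary of a window scan
#'
#' @param x A [bsa_scan()] object.
#' @param ... Unused.
#' @return Tibble with window counts, reliable-window counts per track,
#'   the genome-wide maximum `|mean delta|`, and the number of candidate
#'   regions.
#' @export
glance.bsa_scan <- function(x, ...) {
  tibble(
    n_windows = nrow(x$snp),
    n_reliable_snp = sum(x$snp$reliable),
    n_reliable_indel = sum(x$indel$reliable),
    max_abs_delta_snp = max(abs(x$snp$mean_delta[x$snp$reliable]), na.rm = TRUE),
    max_abs_delta_indel = max(abs(x$indel$mean_delta[x$indel$reliable]), na.rm = TRUE),
    n_regions = nrow(x$regions),
    delta_threshold = x$config$delta_threshold
  )
}

#' Tidy the per-environment haplotype tests
#'
#' @param x A [haplotype_compare()] object.
#' @param ... Unused.
#' @return The per-environment test tibble (group sizes, means, Welch
#'   statistic, p-value, tested flag).
#' @export
tidy.bsa_haplotype <- function(x, ...) x$tests

#' One-row summary of a haplotype comparison
#'
#' @param x A [haplotype_compare()] object.
#' @param ... Unused.
#' @return Tibble with the number of environments tested, the smallest
#'   p-value, and per-type REF fractions spread into columns.
#' @export
glance.bsa_haplotype <- function(x, ...) {
  out <- tibble(
    n_environments = nrow(x$tests),
    n_tested = sum(x$tests$tested),
    min_p = if (any(x$tests$tested)) min(x$tests$p_value, na.rm = TRUE) else NA_real_
  )
  if (nrow(x$ref_fraction) > 0L) {
    wide <- tidyr::pivot_wider(x$ref_fraction[c("accession_type", "ref_fraction")],
                               names_from = "accession_type",
                               values_from = "ref_fraction",
                               names_prefix = "ref_fraction_")
    out <- dplyr::bind_cols(out, wide)
  }
  out
}

#' One-row summary of a pipeline run
#'
#' @param x A [run_bsa_pipeline()] result.
#' @param ... Unused.
#' @return Tibble with retained-site count, region count, top gene and its
#'   rank class, number of significant GO terms, and the smallest haplotype
#'   p-value.
#' @export
glance.bsa_result <- function(x, ...) {
  rep <- filter_report(x$filtered)
  tibble(
    n_sites = sum(rep$removed),
    n_retained = rep$removed[rep$rule == "retained"],
    n_regions = nrow(x$scan$regions),
    top_gene = if (nrow(x$gene_priority) > 0L) x$gene_priority$gene_id[1] else NA_character_,
    top_rank = if (nrow(x$gene_priority) > 0L) x$gene_priority$rank_class[1] else NA_character_,
    n_go_significant = if (!is.null(x$enrichment)) sum(x$enrichment$significant) else 0L,
    min_haplotype_p = if (!is.null(x$haplotype) && any(x$haplotype$tests$tested))
      min(x$haplotype$tests$p_value, na.rm = TRUE) else NA_real_
  )
}
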