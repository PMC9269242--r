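#' Sequencing QC rate arithmetic
#'
#' The two rates a resequencing QC report derives from its raw counts:
#' effective rate = 100 * clean bases / raw bases, and mapping rate =
#' 100 * mapped reads / total reads, both rounded to two decimals.
#'
#' @param raw_bases,clean_bases Base counts before/after read cleaning.
#' @param mapped_reads,total_reads Read counts after alignment.
#' @return Tibble with `effective_rate` and `mapping_rate` (percent, 2 dp);
#'   a rate is `NA` when its inputs are missing.
#' @examples
#' qc_rates(raw_bases = 57765692100, clean_bases = 57645759600,
#'          mapped_reads = 349651428, total_reads = 353800912)
#' @export
qc_rates <- function(raw_bases = NA, clean_bases = NA,
                     mapped_reads = NA, total_reads = NA) {
  eff <- if (is.na(raw_bases) || is.na(clean_bases)) NA_real_ else {
    if (raw_bases <= 0) abort("raw_bases must be positive")
    round(100 * clean_bases / raw_bases, 2)
  }
  mp <- if (is.na(mapped_reads) || is.na(total_reads)) NA_real_ else {
    if (total_reads <= 0) abort("total_reads must be positive")
    round(100 * mapped_reads / total_reads, 2)
  }
  tibble(effective_rate = eff, mapping_rate = mp)
}

#' Transition/transversion bookkeeping
#'
#' Every biallelic SNV is either a transition (purine-purine or
#' pyrimidine-pyrimidine) or a transversion, so the two counts must add up
#' to the SNV total; this helper performs that reconciliation.
#'
#' @param transitions,transversions SNV counts.
#' @return Tibble with `transitions`, `transversions`, `total` and the
#'   `ts_tv` ratio.
#' @export
tstv_summary <- function(transitions, transversions) {
  tibble(transitions = transitions, transversions = transversions,
         total = transitions + transversions,
         ts_tv = transitions / transversions)
}

#' Run the full synthetic BSA-seq pipeline
#'
#' End-to-end seeded run on generated data: toy genome + gene models + GO
#' annotation, cohort simulation, extreme-pool selection, pooled read
#' simulation, index filtering, two-track window scan with simulated CIs,
#' candidate-region calling, consequence classification, gene
#' prioritisation, GO enrichment of the region genes, and the
#' haplotype-phenotype comparison at the top candidate's variant site.
#'
#' @param config A [sim_config()]; its `rng_seed` governs every stochastic
#'   stage.
#' @param filter_cfg A [filter_config()].
#' @param scan_cfg A [scan_config()]; if its `rng_seed` is `NULL` the
#'   simulation seed is reused.
#' @param out_dir Optional directory: write the VCF, GFF3, GO/phenotype
#'   TSVs and all result tables there.
#' @return An object of class `"bsa_result"`: list with `cohort`, `pools`,
#'   `truth`, `filtered` (+ filter report), `scan` (a [bsa_scan()] object),
#'   `effects`, `gene_priority`, `enrichment`, `haplotype`, `config`.
#' @export
run_bsa_pipeline <- function(config = sim_config(),
                             filter_cfg = filter_config(),
                             scan_cfg = scan_config(),
                             out_dir = NULL) {
  toy <- emit_toy_genome(config)
  cohort <- sim_cohort(config, genome = toy$genome)
  pools <- select_pools(cohort)
  reads <- sim_pooled_reads(cohort, pools)

  filtered <- bsa_filter(reads$variants, filter_cfg)
  if (is.null(scan_cfg$rng_seed)) scan_cfg$rng_seed <- config$rng_seed
  scan_cfg$pool_size <- config$n_pool  # the simulated null mirrors the design
  scan <- bsa_scan(filtered, sim_chrom_lengths(config),
                   genes = toy$genes, config = scan_cfg,
                   filter_cfg = filter_cfg)

  region_variants <- filtered[rep(FALSE, nrow(filtered)), ]
  if (nrow(scan$regions) > 0L) {
    keep <- rep(FALSE, nrow(filtered))
    for (r in seq_len(nrow(scan$regions))) {
      keep <- keep | (filtered$chrom == scan$regions$chrom[r] &
                        filtered$pos >= scan$regions$start[r] &
                        filtered$pos <= scan$regions$end[r])
    }
    region_variants <- filtered[keep, ]
  }
  effects <- if (nrow(region_variants) > 0L) {
    classify_variants(region_variants, toy$genes, toy$genome)
  } else {
    NULL
  }
  gene_priority <- if (!is.null(effects)) {
    prioritize_genes(scan$regions, effects)
  } else {
    prioritize_genes(scan$regions[0, ], tibble())
  }

  study_genes <- unique(unlist(scan$regions$genes))
  enrichment <- if (length(study_genes) > 0L) {
    go_enrich(study_genes, toy$go)
  } else {
    NULL
  }

  haplotype <- NULL
  if (nrow(gene_priority) > 0L && !is.na(gene_priority$first_pos[1])) {
    ph <- cohort_phenotype_table(cohort, gene_priority$chrom[1],
                                 gene_priority$first_pos[1])
    haplotype <- haplotype_compare(ph)
  }

  out <- structure(list(cohort = cohort, pools = pools, truth = reads$truth,
                        filtered = filtered, scan = scan, effects = effects,
                        gene_priority = gene_priority,
                        enrichment = enrichment, haplotype = haplotype,
                        toy = toy, config = config),
                   class = "bsa_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pooled_vcf(reads$variants, file.path(out_dir, "pools.vcf"))
    write_gene_models_gff3(toy$genes, file.path(out_dir, "genes.gff3"))
    readr::write_tsv(toy$go, file.path(out_dir, "go_annotation.tsv"), progress = FALSE)
    write_variants_tsv(filtered, file.path(out_dir, "variants_filtered.tsv"))
    readr::write_tsv(filter_report(filtered),
                     file.path(out_dir, "filter_report.tsv"), progress = FALSE)
    readr::write_tsv(scan$snp, file.path(out_dir, "windows_snp.tsv"), progress = FALSE)
    readr::write_tsv(scan$indel, file.path(out_dir, "windows_indel.tsv"), progress = FALSE)
    if (nrow(scan$regions) > 0L) {
      write_regions_bed(scan$regions, file.path(out_dir, "regions.bed"))
      readr::write_tsv(select(scan$regions, -"genes"),
                       file.path(out_dir, "regions.tsv"), progress = FALSE)
    }
    if (!is.null(effects)) write_effects_tsv(effects, file.path(out_dir, "effects.tsv"))
    if (nrow(gene_priority) > 0L) {
      readr::write_tsv(gene_priority, file.path(out_dir, "gene_priority.tsv"),
                       progress = FALSE)
    }
    if (!is.null(enrichment)) {
      readr::write_tsv(select(as_tibble(enrichment), -"gene_ids"),
                       file.path(out_dir, "enrichment.tsv"), progress = FALSE)
    }
    if (!is.null(haplotype)) {
      readr::write_tsv(haplotype$tests, file.path(out_dir, "haplotype_tests.tsv"),
                       progress = FALSE)
    }
  }
  out
}

#' @export
print.bsa_result <- function(x, ...) {
  rep <- filter_report(x$filtered)
  cat(sprintf("<bsa_result> %d sites retained of %d; %d candidate region(s)\n",
              rep$removed[rep$rule == "retained"], sum(rep$removed),
              nrow(x$scan$regions)))
  if (nrow(x$gene_priority) > 0L) {
    cat("top candidate gene:", x$gene_priority$gene_id[1],
        sprintf("(%s)\n", x$gene_priority$rank_class[1]))
  }
  invisible(x)
}
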