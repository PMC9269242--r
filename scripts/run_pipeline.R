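#!/usr/bin/env Rscript

# Thin command-line wrapper over the package pipeline.
#
#   Rscript scripts/run_pipeline.R --stage all --seed 1 --out-dir results/run1
#
# Stages: simulate (write synthetic inputs only) | all (full pipeline).
# Exit codes: 0 success, 2 configuration error, 3 data/stage error.

suppressMessages({
  library(optparse)
  library(bsascan)
})

opts <- tryCatch(
  parse_args(OptionParser(option_list = list(
    make_option("--stage", type = "character", default = "all"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out-dir", type = "character", default = "results/pipeline",
                dest = "out_dir"),
    make_option("--accessions", type = "integer", default = 1525L),
    make_option("--pool-size", type = "integer", default = 49L,
                dest = "pool_size"),
    make_option("--chromosomes", type = "integer", default = 20L),
    make_option("--chrom-length", type = "double", default = 5e6,
                dest = "chrom_length"),
    make_option("--variants", type = "integer", default = 12000L),
    make_option("--depth", type = "double", default = 40),
    make_option("--null-reps", type = "integer", default = 500L,
                dest = "null_reps"),
    make_option("--ld", action = "store_true", default = TRUE),
    make_option("--no-ld", action = "store_false", dest = "ld")
  ))),
  error = function(e) { message("configuration error: ", conditionMessage(e)); quit(status = 2) })

if (!opts$stage %in% c("simulate", "all")) {
  message("configuration error: unknown stage '", opts$stage, "'")
  quit(status = 2)
}

cfg <- sim_config(n_accessions = opts$accessions, n_pool = opts$pool_size,
                  n_chromosomes = opts$chromosomes,
                  chrom_length = opts$chrom_length,
                  n_variants = opts$variants, mean_depth = opts$depth,
                  ld = opts$ld, rng_seed = opts$seed)

status <- tryCatch({
  if (opts$stage == "simulate") {
    toy <- emit_toy_genome(cfg)
    cohort <- sim_cohort(cfg, genome = toy$genome)
    reads <- sim_pooled_reads(cohort, select_pools(cohort))
    dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pooled_vcf(reads$variants, file.path(opts$out_dir, "pools.vcf"))
    write_gene_models_gff3(toy$genes, file.path(opts$out_dir, "genes.gff3"))
    Biostrings::writeXStringSet(toy$genome,
                                file.path(opts$out_dir, "genome.fasta"))
    readr::write_tsv(toy$go, file.path(opts$out_dir, "go_annotation.tsv"))
    readr::write_tsv(reads$truth, file.path(opts$out_dir, "truth.tsv"))
    message("synthetic inputs written to ", opts$out_dir)
  } else {
    res <- run_bsa_pipeline(cfg,
                            scan_cfg = scan_config(null_reps = opts$null_reps),
                            out_dir = opts$out_dir)
    print(generics::glance(res))
    message("results written to ", opts$out_dir)
  }
  0L
}, error = function(e) { message("stage error: ", conditionMessage(e)); 3L })

quit(status = status)
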