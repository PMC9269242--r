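# scaled-down cohorts keep these tests fast; the full-size design is
# exercised by the acceptance suite

small_cfg <- function(...) {
  sim_config(n_accessions = 300, n_pool = 30, n_chromosomes = 2,
             chrom_length = 1e6, n_variants = 400,
             causal_sites = data.frame(chrom = "Chr02", pos = 5e5,
                                       effect = 40, freq = 0.4), ...)
}

test_that("cohort simulation is seeded, Hardy-Weinberg, and phenotype-faithful", {
  cfg <- small_cfg(rng_seed = 42)
  co1 <- sim_cohort(cfg)
  co2 <- sim_cohort(cfg)
  expect_identical(co1$genotypes, co2$genotypes)
  expect_identical(co1$phenotypes, co2$phenotypes)

  expect_true(all(co1$genotypes %in% 0:2))
  expect_true(all(is.finite(co1$phenotypes)))
  expect_equal(dim(co1$phenotypes), c(300L, 5L))
  expect_equal(sum(co1$sites$causal), 1L)

  # genotype frequencies follow the drawn allele frequencies
  emp <- colMeans(co1$genotypes) / 2
  expect_lt(max(abs(emp - co1$sites$freq)), 0.12)

  # null model: zero effect means no genotype-phenotype association
  cfg0 <- small_cfg(rng_seed = 43)
  cfg0$causal_sites$effect <- 0
  co0 <- sim_cohort(cfg0)
  j <- which(co0$sites$causal)
  slope <- coef(lm(co0$phenotypes[, 1] ~ co0$genotypes[, j]))[2]
  expect_lt(abs(slope), 10)
})

test_that("single-locus heritability matches the closed form within 10%", {
  # h2 = 2p(1-p)a^2 / (2p(1-p)a^2 + sigma_e^2); a = 40, p = 0.4, s = 35
  h2_closed <- (2 * 0.4 * 0.6 * 40^2) / (2 * 0.4 * 0.6 * 40^2 + 35^2)
  expect_equal(round(h2_closed, 3), 0.385)
  cfg <- sim_config(n_accessions = 1525, n_pool = 49, n_chromosomes = 1,
                    chrom_length = 1e6, n_variants = 10,
                    causal_sites = data.frame(chrom = "Chr01", pos = 5e5,
                                              effect = 40, freq = 0.4),
                    rng_seed = 7)
  co <- sim_cohort(cfg)
  j <- which(co$sites$causal)
  g_val <- 40 * co$genotypes[, j]
  h2_emp <- var(g_val) / var(co$phenotypes[, 1])
  expect_lt(abs(h2_emp - h2_closed) / h2_closed, 0.10)
})

test_that("pool selection takes phenotype extremes with deterministic ties", {
  cfg <- small_cfg(rng_seed = 1)
  co <- sim_cohort(cfg)
  # forced phenotypes 1..300 on a single environment
  co$phenotypes <- matrix(1:300, ncol = 1,
                          dimnames = list(co$accessions$accession_id, "E1"))
  p <- select_pools(co, n_pool = 3)
  expect_equal(p$high, co$accessions$accession_id[300:298])
  expect_equal(p$low, co$accessions$accession_id[1:3])

  # all-equal phenotypes: deterministic id-ordered split, disjoint
  co$phenotypes[] <- 5
  p2 <- select_pools(co, n_pool = 10)
  ids <- sort(co$accessions$accession_id)
  expect_equal(p2$low, ids[1:10])
  expect_equal(p2$high, rev(ids)[1:10])
  expect_equal(length(intersect(p2$high, p2$low)), 0L)

  # default scenario separates the pools far beyond the noise scale
  co3 <- sim_cohort(small_cfg(rng_seed = 3))
  p3 <- select_pools(co3)
  m <- rowMeans(co3$phenotypes)
  expect_gt(mean(m[match(p3$high, co3$accessions$accession_id)]) -
              mean(m[match(p3$low, co3$accessions$accession_id)]),
            2 * co3$config$sigma_e)
})

test_that("pooled reads are binomial draws around the true pool frequencies", {
  cfg <- small_cfg(rng_seed = 11, seq_error = 0)
  co <- sim_cohort(cfg)
  pools <- select_pools(co)
  reads <- sim_pooled_reads(co, pools)
  # truth and observation align on average at the causal site over resamples
  j <- which(reads$truth$causal)
  set.seed(1)
  deltas <- replicate(1000, {
    r <- sim_pooled_reads(co, pools)
    with(r$variants[j, ],
         ad_high_alt / (ad_high_ref + ad_high_alt) -
           ad_low_alt / (ad_low_ref + ad_low_alt))
  })
  expect_lt(abs(mean(deltas) - reads$truth$delta_true[j]), 0.02)

  # monomorphic REF site with no error never shows ALT reads
  co_mono <- co
  co_mono$genotypes[, 1] <- 0L
  r0 <- sim_pooled_reads(co_mono, pools)
  expect_equal(r0$variants$ad_high_alt[1], 0L)
  expect_equal(r0$variants$ad_low_alt[1], 0L)

  # Poisson depth with the configured mean
  big <- sim_config(n_accessions = 50, n_pool = 10, n_chromosomes = 1,
                    chrom_length = 1e6, n_variants = 2000,
                    causal_sites = data.frame(chrom = "Chr01", pos = 5e5,
                                              effect = 0, freq = 0.4),
                    rng_seed = 5)
  rb <- sim_pooled_reads(sim_cohort(big), list(high = sprintf("ACC%04d", 1:10),
                                               low = sprintf("ACC%04d", 11:20)))
  depth <- rb$variants$ad_high_ref + rb$variants$ad_high_alt
  expect_lt(abs(mean(depth) - 40), 1)
})

test_that("truth-table divergence grows with the causal effect size", {
  deltas <- vapply(c(5, 20, 40, 80), function(a) {
    cfg <- small_cfg(rng_seed = 99)
    cfg$causal_sites$effect <- a
    co <- sim_cohort(cfg)
    r <- sim_pooled_reads(co, select_pools(co))
    r$truth$delta_true[r$truth$causal]
  }, numeric(1))
  expect_true(all(diff(deltas) >= 0))
  expect_gt(deltas[4], deltas[1])
})

test_that("the toy genome hosts six candidate-region genes and a non-synonymous causal SNV", {
  cfg <- sim_config(n_accessions = 100, n_pool = 10, n_chromosomes = 6,
                    chrom_length = 2e6,
                    causal_sites = data.frame(chrom = "Chr05", pos = 1e6,
                                              effect = 40, freq = 0.4),
                    n_variants = 100, rng_seed = 8)
  toy <- emit_toy_genome(cfg)
  in_region <- toy$genes$chrom == toy$region$chrom &
    toy$genes$tx_start <= toy$region$end & toy$genes$tx_end >= toy$region$start
  expect_equal(sum(in_region), 6L)

  cv <- toy$causal_variant
  eff <- classify_variants(
    tibble::tibble(chrom = cv$chrom, pos = cv$pos, ref = cv$ref, alt = cv$alt,
                   vclass = "SNP"), toy$genes, toy$genome)
  expect_equal(eff$category, "exonic")
  expect_equal(eff$exonic_subtype, "non-synonymous")
  expect_equal(eff$gene_id, toy$causal_gene)

  # seeded emission is identical
  toy2 <- emit_toy_genome(cfg)
  expect_identical(as.character(toy$genome), as.character(toy2$genome))
  expect_identical(toy$go, toy2$go)

  # sites drawn against the genome carry matching REF alleles
  co <- sim_cohort(cfg, genome = toy$genome)
  i <- sample.int(nrow(co$sites), 20)
  for (k in i) {
    base <- as.character(Biostrings::subseq(
      toy$genome[[co$sites$chrom[k]]], co$sites$pos[k], co$sites$pos[k]))
    expect_equal(substr(co$sites$ref[k], 1, 1), base)
  }
})

test_that("pooled VCF writing round-trips through the VCF reader", {
  cfg <- small_cfg(rng_seed = 31)
  co <- sim_cohort(cfg)
  r <- sim_pooled_reads(co, select_pools(co))
  path <- tempfile(fileext = ".vcf")
  write_pooled_vcf(r$variants, path)
  back <- read_pooled_vcf(path)
  v <- dplyr::arrange(r$variants, chrom, pos)
  expect_equal(back$chrom, v$chrom)
  expect_equal(back$pos, v$pos)
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
  expect_equal(back$ad_high_ref, v$ad_high_ref)
  expect_equal(back$ad_high_alt, v$ad_high_alt)
  expect_equal(back$ad_low_ref, v$ad_low_ref)
  expect_equal(back$ad_low_alt, v$ad_low_alt)
  expect_equal(back$vclass, v$vclass)
})
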